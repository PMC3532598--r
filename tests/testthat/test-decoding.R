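# Linear-margin decoding: solver correctness (KKT conditions plus agreement
# with an independent SVM implementation), fold structure, nested C
# selection, condition-split subject decoding and group aggregation.

test_that("leave-one-session-out folds partition the sessions", {
  f4 <- loso_folds(rep(1:4, each = 5))
  expect_length(f4, 4)
  expect_setequal(vapply(f4, `[[`, numeric(1), "test_session"), 1:4)
  for (f in f4) {
    expect_length(f$train_sessions, 3)
    expect_false(f$test_session %in% f$train_sessions)
  }
  f2 <- loso_folds(c(1, 1, 2, 2))
  expect_length(f2, 2)
  expect_error(loso_folds(rep(1, 6)), "2 sessions")
})

test_that("the solver separates a trivial problem with positive margin", {
  x <- matrix(c(1, -1, 0, 0), 2, 2)
  fit <- train_linear_margin(x, c("pain", "no_pain"), C = 10)
  expect_equal(predict(fit, x), c("pain", "no_pain"))
  expect_gt(predict(fit, x, type = "decision")[1], 0)
  expect_lt(predict(fit, x, type = "decision")[2], 0)
  expect_error(train_linear_margin(x, c("pain", "pain")), "both classes")
})

test_that("solutions satisfy the KKT conditions of the soft-margin dual", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(6:20, 1); V <- sample(2:10, 1); C <- sample(c(0.1, 1, 10), 1)
    x <- matrix(rnorm(n * V), n, V)
    y <- sample(rep_len(c(1, -1), n))
    fit <- train_linear_margin(x, y, C = C, eps = 1e-8)
    marg <- y * (x %*% fit$w + fit$b)
    a <- fit$alpha
    tol <- 1e-4
    expect_true(all(a >= -1e-12 & a <= C + 1e-12))
    expect_lt(abs(sum(a * y)), 1e-8)
    expect_true(all(marg[a < 1e-8] >= 1 - tol))
    free <- a > 1e-8 & a < C - 1e-8
    if (any(free)) expect_lt(max(abs(marg[free] - 1)), tol)
    expect_true(all(marg[a > C - 1e-8] <= 1 + tol))
  }
})

test_that("the solver agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  for (i in 1:8) {
    n <- sample(8:24, 1); V <- sample(2:12, 1)
    C <- sample(c(0.01, 0.1, 1, 10), 1)
    x <- matrix(rnorm(n * V), n, V)
    y <- sample(rep_len(c(1, -1), n))
    fit <- train_linear_margin(x, y, C = C, eps = 1e-8)
    ref <- e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = C, scale = FALSE, tolerance = 1e-6)
    w_ref <- drop(crossprod(ref$SV, ref$coefs))
    # libsvm orients its decision function by the first training label
    s <- if (y[1] == 1) 1 else -1
    expect_equal(fit$w, s * w_ref, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(fit$b, s * -ref$rho, tolerance = 1e-4)
  }
})

test_that("duplicating features splits weights, leaving predictions unchanged", {
  set.seed(3)
  x <- matrix(rnorm(10 * 4), 10, 4)
  y <- rep(c(1, -1), 5)
  x <- x + 2 * y   # separable: the margin, not the slack, drives the fit
  f1 <- train_linear_margin(x, y, C = 10)
  f2 <- train_linear_margin(cbind(x, x), y, C = 10)
  expect_equal(predict(f1, x), predict(f2, cbind(x, x)))
  # each duplicate carries half the weight
  expect_equal(f2$w[1:4], f2$w[5:8], tolerance = 1e-6)
})

test_that("flipping all labels negates the decision values", {
  set.seed(4)
  x <- matrix(rnorm(12 * 5), 12, 5)
  y <- rep(c(1, -1), 6)
  f1 <- train_linear_margin(x, y, C = 1, eps = 1e-8)
  f2 <- train_linear_margin(x, -y, C = 1, eps = 1e-8)
  expect_equal(predict(f1, x, type = "decision"),
               -predict(f2, x, type = "decision"), tolerance = 1e-6)
})

test_that("nested C selection matches a brute-force inner loop", {
  set.seed(5)
  # class separation keeps decision values away from zero, where solutions
  # that differ within the solver tolerance could flip a prediction
  x <- matrix(rnorm(10 * 3), 10, 3) + 0.8 * rep(c(1, -1), 5)
  y <- rep(c("pain", "no_pain"), 5)
  grid <- c(0.01, 1, 100)
  sel <- nested_select_C(x, y, grid)
  # independent leave-one-trial-out loop over the same grid
  oracle <- vapply(grid, function(C) {
    correct <- vapply(1:10, function(t) {
      fit <- train_linear_margin(x[-t, ], y[-t], C = C)
      predict(fit, x[t, , drop = FALSE]) == y[t]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  expect_equal(unname(sel$inner_accuracy), oracle)
  expect_equal(sel$C, grid[which.max(oracle)])
})

test_that("C selection tie-breaks to the smallest candidate", {
  set.seed(6)
  x <- rbind(matrix(5, 4, 2), matrix(-5, 4, 2)) +
    matrix(rnorm(16, sd = 0.01), 8, 2)
  y <- rep(c("pain", "no_pain"), each = 4)
  sel <- nested_select_C(x, y, c(0.5, 5, 50))
  expect_equal(unname(sel$inner_accuracy), rep(1, 3))  # all separate perfectly
  expect_equal(sel$C, 0.5)
  one <- nested_select_C(x, y, 7)
  expect_equal(one$C, 7)
  expect_error(nested_select_C(x, y, numeric(0)), "nonempty")
})

test_that("a separable subject decodes perfectly and averages strata", {
  b <- toy_beta(n_sessions = 3, trials_per_session = 8, V = 10,
                effect = 30, seed = 10)
  d <- decode_subject(b, "stimulation")
  expect_equal(d$mean_accuracy, 1)
  expect_equal(unname(d$stratum_accuracy), c(1, 1))
  expect_equal(d$mean_accuracy, mean(d$stratum_accuracy))
  # every trial predicted exactly once
  expect_equal(nrow(d$predictions), 24)
  expect_false(anyNA(d$predictions$pred))
})

test_that("the subject value is the arithmetic mean of stratum accuracies", {
  b <- toy_beta(n_sessions = 2, trials_per_session = 10, V = 8,
                effect = 1.2, seed = 11)
  d <- decode_subject(b, "stimulation", quiet = TRUE, undecodable = "na")
  expect_equal(d$mean_accuracy, mean(d$stratum_accuracy))
})

test_that("a null subject decodes near chance", {
  b <- toy_beta(n_sessions = 2, trials_per_session = 12, V = 10,
                effect = 0, seed = 12)
  d <- decode_subject(b, "stimulation", quiet = TRUE, undecodable = "na")
  # binomial 95% band around 0.5 for 24 trials, with margin
  expect_gt(d$mean_accuracy, 0.2)
  expect_lt(d$mean_accuracy, 0.8)
})

test_that("decoding is invariant to a positive rescaling of the patterns", {
  b <- toy_beta(n_sessions = 2, trials_per_session = 8, V = 6,
                effect = 1, seed = 13)
  b2 <- b
  b2$patterns <- lapply(b$patterns, function(p) 17 * p)
  d1 <- decode_subject(b, "stimulation", quiet = TRUE, undecodable = "na")
  d2 <- decode_subject(b2, "stimulation", quiet = TRUE, undecodable = "na")
  expect_equal(d1$mean_accuracy, d2$mean_accuracy)
  expect_equal(d1$folds$chosen_C, d2$folds$chosen_C)
  expect_equal(d1$predictions$pred, d2$predictions$pred)
})

test_that("group aggregation is the arithmetic mean with SEM", {
  g <- group_accuracy(c(0.5, 0.7))
  expect_equal(g$mean_accuracy, 0.6)
  expect_equal(group_accuracy(c(0.5, 0.5, 0.5))$mean_accuracy, 0.5)
  expect_equal(g$sem, sd(c(0.5, 0.7)) / sqrt(2))
  expect_error(group_accuracy(0.6), "2 subjects")
})

test_that("group decoding of a planted simulated group is near ceiling", {
  sim <- sim_group_fixture()
  g <- decode_group(sim$betas, "stimulation", feature_spec("whole_brain"),
                    decoding_config(), N_perm = 19, seed = 1)
  expect_gt(g$mean_accuracy, 0.75)
  expect_equal(g$p, perm_pvalue(g$mean_accuracy, attr(g, "null")))
  # anticipation carries no planted signal in this fixture
  g0 <- decode_group(sim$betas, "anticipation", feature_spec("whole_brain"),
                     decoding_config(), N_perm = 0)
  expect_lt(abs(g0$mean_accuracy - 0.5), 0.25)
})

test_that("ROI and top-voxel feature spaces decode the planted fixture", {
  sim <- sim_group_fixture()
  cfg <- decoding_config()
  roi <- decode_group(sim$betas, "stimulation", feature_spec("roi", "R01"), cfg)
  ctrl <- decode_group(sim$betas, "stimulation", feature_spec("roi", "CTRL1"), cfg)
  expect_gt(roi$mean_accuracy, ctrl$mean_accuracy)
  top <- decode_group(sim$betas, "stimulation",
                      feature_spec("top_voxels", k = 9), cfg)
  expect_gt(top$mean_accuracy, 0.7)
})
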