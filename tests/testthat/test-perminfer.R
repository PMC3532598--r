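# Permutation inference: within-session shuffles, p-value formula,
# permutation counts, weight nulls against an enumeration oracle, the
# normality audit, FWE thresholds and paired comparisons.

test_that("within-session shuffles preserve per-session label counts", {
  labels <- c("pain", "pain", "no_pain", "no_pain", "pain", "no_pain")
  sessions <- c(1, 1, 1, 2, 2, 2)
  set.seed(1)
  for (i in 1:20) {
    p <- permute_within_sessions(labels, sessions)
    expect_equal(table(p[1:3]), table(labels[1:3]))
    expect_equal(table(p[4:6]), table(labels[4:6]))
  }
  # a session with identical labels is unchanged
  expect_identical(permute_within_sessions(rep("pain", 4), rep(1, 4)),
                   rep("pain", 4))
})

test_that("all within-session arrangements are equally likely", {
  labels <- c("pain", "no_pain", "pain", "no_pain")
  sessions <- c(1, 1, 2, 2)
  set.seed(2)
  draws <- replicate(4000, paste(permute_within_sessions(labels, sessions),
                                 collapse = ","))
  tab <- table(draws)
  expect_length(tab, 4)   # 2 arrangements per session
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("the permutation p-value is a tie-inclusive rank with 1/N floor", {
  expect_equal(perm_pvalue(0.55, c(0.4, 0.5, 0.6)), 1 / 3)
  expect_equal(perm_pvalue(0.3, c(0.4, 0.5, 0.6)), 1)
  null1000 <- seq(0, 0.999, length.out = 1000)
  expect_equal(perm_pvalue(1.5, null1000), 0.001)   # beats all: floor 1/N
  # brute-force equality on random instances, and monotonicity
  set.seed(3)
  for (i in 1:200) {
    null <- round(runif(sample(5:50, 1)), 2)
    obs <- round(runif(1), 2)
    expect_identical(perm_pvalue(obs, null),
                     max(sum(null >= obs), 1L) / length(null))
  }
  null <- runif(99)
  obs <- sort(runif(20))
  p <- vapply(obs, perm_pvalue, numeric(1), null = null)
  expect_true(all(diff(p) <= 0))
})

test_that("required permutation counts match the detectability bound", {
  expect_equal(required_N(0.05, 1), 20L)
  expect_equal(required_N(0.001, 1), 1000L)
  expect_equal(required_N(0.05, 26), 520L)
  expect_true(all(1 / required_N(0.05, 1:30) <= 0.05 / (1:30) + 1e-12))
})

test_that("subject-level accuracy nulls are reproducible and centred", {
  b <- toy_beta(n_sessions = 2, trials_per_session = 10, V = 8,
                effect = 0, seed = 20)
  dec <- make_subject_decoder(b, "stimulation")
  null1 <- accuracy_null(dec, b$meta$label, b$meta$session, N = 30, seed = 5)
  null2 <- accuracy_null(dec, b$meta$label, b$meta$session, N = 30, seed = 5)
  expect_identical(null1, null2)
  expect_length(accuracy_null(dec, b$meta$label, b$meta$session, 1, 1), 1)
  expect_lt(abs(mean(null1, na.rm = TRUE) - 0.5), 0.1)
})

test_that("weight nulls match exhaustive enumeration on a small instance", {
  set.seed(6)
  x <- matrix(rnorm(18), 6, 3)
  labels <- c("pain", "pain", "no_pain", "pain", "no_pain", "no_pain")
  sessions <- c(1, 1, 1, 2, 2, 2)
  wn <- weight_null(x, labels, sessions, C = 1, exhaustive = TRUE)
  expect_equal(wn$N, 9)   # 3 arrangements per session
  # independent oracle: enumerate label arrangements by hand
  per_session <- list(combn(3, 2), combn(3, 1))   # positions of 'pain'
  draws <- NULL
  for (i in seq_len(ncol(per_session[[1]]))) {
    for (j in seq_len(ncol(per_session[[2]]))) {
      y <- rep("no_pain", 6)
      y[per_session[[1]][, i]] <- "pain"
      y[3 + per_session[[2]][, j]] <- "pain"
      draws <- rbind(draws, train_linear_margin(x, y, C = 1)$w)
    }
  }
  expect_equal(sort(wn$mu), sort(colMeans(draws)), tolerance = 1e-10)
  expect_equal(wn$mu, colMeans(draws), tolerance = 1e-10)
  expect_equal(wn$sd, apply(draws, 2, sd), tolerance = 1e-10)
  # t-scores from the same enumeration
  fit <- train_linear_margin(x, labels, C = 1)
  tm <- weight_tscores(fit$w, wn)
  expect_equal(tm$t, (fit$w - colMeans(draws)) / apply(draws, 2, sd),
               tolerance = 1e-10)
  expect_equal(tm$df, 8)
})

test_that("degenerate nulls (no label mixing) are flagged", {
  x <- matrix(rnorm(12), 4, 3)
  labels <- c("pain", "pain", "no_pain", "no_pain")
  sessions <- c(1, 1, 2, 2)   # sessions are single-class: only one arrangement
  wn <- weight_null(x, labels, sessions, N = 2, seed = 1)
  expect_equal(length(wn$flagged), 3)
  tm <- weight_tscores(train_linear_margin(x, labels)$w, wn)
  expect_true(all(is.na(tm$t)))
  expect_equal(tm$n_flagged, 3)
})

test_that("t-scores and p-values follow the null-standardization formula", {
  wn <- structure(list(mu = c(1, 2), sd = c(0.5, 2), N = 100,
                       flagged = integer(0), draws = NULL, C = 1),
                  class = "weight_null")
  tm <- weight_tscores(c(1, 6), wn)
  expect_equal(tm$t, c(0, 2))
  expect_equal(tm$p[1], 1)
  expect_equal(tm$p, 2 * pt(-abs(tm$t), 99), tolerance = 1e-10)
})

test_that("null weights stay inside their own null bulk on null data", {
  set.seed(7)
  x <- matrix(rnorm(16 * 30), 16, 30)
  labels <- sample(rep(c("pain", "no_pain"), 8))
  sessions <- rep(1:2, each = 8)
  fit <- train_linear_margin(x, labels, C = 1)
  wn <- weight_null(x, labels, sessions, N = 199, C = 1, seed = 8)
  tm <- weight_tscores(fit$w, wn)
  expect_gte(mean(abs(tm$t) < 2.5, na.rm = TRUE), 0.9)
})

test_that("the normality audit has its nominal size and detects violations", {
  set.seed(9)
  gauss <- matrix(rnorm(100 * 300), 100, 300)
  fr <- normality_fraction(gauss, alpha = 0.05)
  expect_gt(fr, 0.01); expect_lt(fr, 0.10)
  # the plug-in KS variant is conservative by construction
  fr_ks <- normality_fraction(gauss[, 1:100], alpha = 0.05,
                              method = "ks_plugin")
  expect_lt(fr_ks, fr + 0.05)
  heavy <- matrix(rt(100 * 100, df = 2), 100, 100)
  expect_gt(normality_fraction(heavy, alpha = 0.05), 0.3)
  degen <- matrix(1, 50, 3)
  expect_equal(normality_fraction(degen), 1)
})

test_that("Bonferroni FWE thresholds scale with the voxel count", {
  wn <- structure(list(mu = rep(0, 10), sd = rep(1, 10), N = 100,
                       flagged = integer(0), draws = NULL, C = 1),
                  class = "weight_null")
  tm <- weight_tscores(c(rep(0, 9), 10), wn)
  fw <- fwe_threshold(tm, alpha = 0.05)
  expect_equal(fw$per_voxel_alpha, 0.005)
  expect_equal(fw$threshold, qt(1 - 0.0025, 99))
  expect_equal(fw$mask_pos, 10L)
  expect_length(fw$mask_neg, 0)
  # V = 1: threshold equals the uncorrected two-sided level
  tm1 <- weight_tscores(0.5, structure(list(mu = 0, sd = 1, N = 100,
                                            flagged = integer(0), draws = NULL,
                                            C = 1), class = "weight_null"))
  expect_equal(fwe_threshold(tm1, 0.05)$threshold, qt(1 - 0.025, 99))
  expect_error(fwe_threshold(tm, alpha = 1.5), "alpha")
})

test_that("the random-field threshold needs a grid and exceeds uncorrected", {
  set.seed(10)
  wn <- structure(list(mu = rep(0, 4 * 4 * 4), sd = rep(1, 64), N = 200,
                       flagged = integer(0), draws = NULL, C = 1),
                  class = "weight_null")
  tm <- weight_tscores(rnorm(64), wn)
  expect_error(fwe_threshold(tm, method = "rft"), "grid_shape")
  tm$grid_shape <- c(4, 4, 4)
  fw <- fwe_threshold(tm, method = "rft", fwhm_vox = c(2, 2, 2))
  expect_gt(fw$threshold, qt(1 - 0.025, 199))
  # smoother fields need lower thresholds
  fw2 <- fwe_threshold(tm, method = "rft", fwhm_vox = c(4, 4, 4))
  expect_lt(fw2$threshold, fw$threshold)
})

test_that("paired comparisons enumerate sign flips correctly", {
  a <- c(0.6, 0.62, 0.58, 0.61)
  expect_equal(paired_accuracy_comparison(a, a), 1)
  b <- c(0.55, 0.57, 0.60, 0.52)
  p <- paired_accuracy_comparison(a, b, exact = TRUE)
  # oracle: all 16 sign patterns
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  null <- abs(signs %*% d) / 4
  expect_equal(p, mean(null >= abs(mean(d)) - 1e-12))
  # large constant shift across 16 subjects is maximally significant
  set.seed(11)
  a16 <- runif(16, 0.55, 0.65); b16 <- a16 - 0.2
  expect_lte(paired_accuracy_comparison(a16, b16, N = 1000, seed = 1), 0.001)
  expect_error(paired_accuracy_comparison(0.5, 0.6), "2 subjects")
})
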