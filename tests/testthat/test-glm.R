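# Trial-wise GLM: HRF shape, design construction, filtering, AR(1)
# whitening, estimation against closed-form solutions, smoothing.

test_that("the canonical HRF has the expected shape and sampling", {
  h3 <- hrf_kernel(3)
  expect_length(h3, 11)          # 0, 3, ..., 30 s
  expect_equal(h3[1], 0)
  fine <- hrf_kernel(0.01)
  t_peak <- (which.max(fine) - 1) * 0.01
  expect_lt(abs(t_peak - 5), 0.2)
  # undershoot present and small relative to the peak
  expect_lt(min(fine), 0)
  expect_lt(abs(min(fine)) / max(fine), 0.3)
})

test_that("designs carry two regressors per trial plus session constants", {
  ev <- generate_events(4, 30, seed = 3)
  d <- build_trialwise_design(ev, TR = 3)
  expect_equal(sum(d$kind == "trial_anticipation"), 120)
  expect_equal(sum(d$kind == "trial_stimulation"), 120)
  expect_equal(sum(d$kind != "constant"), 240)
  expect_equal(sum(d$kind == "constant"), 4)
  expect_equal(ncol(d$X), 244)
  expect_equal(nrow(d$X), sum(d$n_volumes))
  # trial regressors vanish outside their session
  first_sess_rows <- d$sessions == 1
  late_col <- which(d$trial == 120)[1]
  expect_true(all(d$X[first_sess_rows, late_col] == 0))
})

test_that("a zero-trial design is constant-only and over-long events error", {
  empty <- data.frame(session = integer(0), trial = integer(0),
                      anticipation_onset = numeric(0),
                      anticipation_duration = numeric(0),
                      stimulation_onset = numeric(0),
                      stimulation_duration = numeric(0),
                      label = character(0), threat = character(0))
  d <- build_trialwise_design(empty, TR = 2, n_volumes = c(10, 12))
  expect_equal(d$kind, c("constant", "constant"))
  expect_equal(colSums(d$X), c(10, 12), ignore_attr = TRUE)
  ev <- generate_events(2, 3, seed = 1)
  expect_error(build_trialwise_design(ev, TR = 3, n_volumes = c(2, 2)),
               "beyond scan end")
})

test_that("a single noiseless trial is recovered exactly", {
  ev <- generate_events(2, 2, seed = 4)
  d <- build_trialwise_design(ev, TR = 3)
  amp <- c(2, 5, -1, 3, 0.5, 1, 4, -2)   # antic/stim per trial
  y <- d$X[, d$kind != "constant"] %*% amp + 7
  bs <- fit_glm(y, d, highpass = FALSE, ar1 = FALSE)
  got <- as.vector(rbind(bs$patterns$anticipation[, 1],
                         bs$patterns$stimulation[, 1]))
  expect_equal(got, amp, tolerance = 1e-10)
})

test_that("the DCT high-pass filter removes slow components only", {
  TR <- 2; n <- 200
  t <- (seq_len(n) - 1) * TR
  expect_equal(highpass_dct(rep(3, n), TR), rep(0, n), tolerance = 1e-12)
  slow <- cos(2 * pi * t / 256)
  filtered <- highpass_dct(slow, TR)
  expect_lt(stats::var(filtered) / stats::var(slow), 0.01)
  # equals the explicit residual-forming projection
  D <- painscale:::dct_basis(n, TR, 128)
  expect_equal(filtered, drop(slow - D %*% crossprod(D, slow)),
               tolerance = 1e-12)
  fast <- cos(2 * pi * t / 20)
  expect_gt(stats::var(highpass_dct(fast, TR)), 0.9 * stats::var(fast))
  set.seed(1)
  w <- rnorm(n)
  expect_lte(stats::var(highpass_dct(w, TR)), stats::var(w))
  expect_error(highpass_dct(w, TR, cutoff_s = 3), "exceed")
  expect_error(highpass_dct(c(1), TR), "2 time points")
})

test_that("AR(1) estimation recovers the generating coefficient", {
  set.seed(11)
  w <- rnorm(1e4)
  expect_lt(abs(ar1_fit_whiten(w)$rho), 0.05)
  x <- as.numeric(stats::filter(rnorm(1e4), 0.3, method = "recursive"))
  expect_lt(abs(ar1_fit_whiten(x)$rho - 0.3), 0.05)
  # rho = 0 gives the identity transform
  alt <- rep(c(1, 0), 10)        # lag-1 products are all zero
  f0 <- ar1_fit_whiten(alt)
  expect_equal(f0$rho, 0)
  expect_equal(f0$whiten(alt), alt)
  # the pooled estimator is bounded inside (-1, 1) even at a unit root
  rw <- cumsum(rnorm(500))
  fr <- ar1_fit_whiten(rw)
  expect_gt(fr$rho, 0.9)
  expect_lt(fr$rho, 1)
})

test_that("whitening applied to data and design preserves exact recovery", {
  ev <- generate_events(2, 4, seed = 8)
  d <- build_trialwise_design(ev, TR = 3)
  amp <- rnorm(16)
  y <- d$X[, d$kind != "constant"] %*% amp
  bs <- fit_glm(y, d, highpass = TRUE, ar1 = TRUE)
  got <- as.vector(rbind(bs$patterns$anticipation[, 1],
                         bs$patterns$stimulation[, 1]))
  expect_equal(got, amp, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  ev <- generate_events(2, 2, seed = 4)
  d <- build_trialwise_design(ev, TR = 3)
  dup <- which(d$kind != "constant")[1:2]
  d$X[, dup[2]] <- d$X[, dup[1]]
  expect_error(fit_glm(matrix(rnorm(nrow(d$X) * 2), ncol = 2), d,
                       highpass = FALSE, ar1 = FALSE),
               "t001_stim")
})

test_that("a simulated subject yields one beta row per trial and phase", {
  sim <- sim_group_fixture()
  bs <- sim$betas[[1]]
  expect_s3_class(bs, "beta_series")
  expect_equal(nrow(bs$patterns$anticipation), 20)
  expect_equal(nrow(bs$patterns$stimulation), 20)
  expect_equal(nrow(bs$meta), 20)
  expect_true(all(is.finite(bs$patterns$stimulation)))
})

test_that("Gaussian smoothing preserves constants and has the right width", {
  vol <- array(2.5, c(9, 9, 9))
  expect_equal(smooth_gaussian(vol, 6, 3), vol, tolerance = 1e-12)
  expect_identical(smooth_gaussian(vol, 0, 3), vol)
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- smooth_gaussian(imp, 12, 3)   # 4-voxel FWHM
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  width <- sum(prof >= half)
  expect_lt(abs(width - 4), 1.5)
  # mass is conserved away from edges (edge renormalization is approximate)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
})
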