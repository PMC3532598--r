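# Permutation inference. Exchangeability holds within sessions under
# leave-one-session-out cross-validation, so labels are always shuffled
# within sessions. Accuracy p-values are rank-based with a 1/N floor and
# ties counted against the observed value (never anticonservative at the
# stated level, attains 1/N). Weight-map inference summarizes each voxel's
# permutation null as Gaussian and refers the standardized observed weight
# to a t distribution on N-1 degrees of freedom.

#' Permute labels within sessions
#'
#' Independent uniform shuffle inside each session; per-session label
#' multisets are preserved, which is the exchangeability structure the
#' leave-one-session-out permutation test requires.
#'
#' @param labels label vector.
#' @param sessions aligned per-trial session index.
#' @return Permuted label vector.
#' @export
permute_within_sessions <- function(labels, sessions) {
  if (length(labels) != length(sessions))
    stop("labels and sessions must be aligned")
  for (s in unique(sessions)) {
    idx <- which(sessions == s)
    labels[idx] <- labels[idx][sample.int(length(idx))]
  }
  labels
}

#' Null distribution of a subject's decoding accuracy
#'
#' Re-runs the identical decoding pipeline (scaling, fold-wise ranking,
#' nested C selection, training, testing) on `N` within-session label
#' permutations.
#'
#' @param decoder a function of the label vector returning an accuracy, as
#'   produced by [make_subject_decoder()] (its `mean_accuracy` is used), or
#'   any function returning a single number.
#' @param labels observed labels.
#' @param sessions per-trial session index.
#' @param N number of permutations (>= 1).
#' @param seed optional seed; fixed seeds reproduce the null vector exactly.
#' @return Numeric vector of `N` permuted accuracies.
#' @export
accuracy_null <- function(decoder, labels, sessions, N, seed = NULL) {
  stopifnot(N >= 1)
  with_seed(seed, vapply(seq_len(N), function(i) {
    res <- decoder(permute_within_sessions(labels, sessions))
    if (is.list(res)) res$mean_accuracy else as.numeric(res)
  }, numeric(1)))
}

#' Null distribution of the group mean accuracy
#'
#' For each permutation, every subject's labels are permuted within sessions
#' independently and the group mean accuracy recorded.
#'
#' @param decoders list of per-subject decoder functions
#'   ([make_subject_decoder()]).
#' @param labels,sessions lists of per-subject label and session vectors.
#' @param N number of permutations.
#' @param seed optional seed.
#' @param na_rm drop subjects whose permuted stratum became undecodable from
#'   that permutation's mean (rare, degenerate shuffles).
#' @return Numeric vector of `N` permuted group means.
#' @export
group_accuracy_null <- function(decoders, labels, sessions, N, seed = NULL,
                                na_rm = TRUE) {
  stopifnot(length(decoders) == length(labels),
            length(decoders) == length(sessions), N >= 1)
  ns <- length(decoders)
  with_seed(seed, vapply(seq_len(N), function(i) {
    acc <- vapply(seq_len(ns), function(j) {
      res <- decoders[[j]](permute_within_sessions(labels[[j]], sessions[[j]]))
      if (is.list(res)) res$mean_accuracy else as.numeric(res)
    }, numeric(1))
    mean(acc, na.rm = na_rm)
  }, numeric(1)))
}

#' Permutation p-value
#'
#' The rank of the observed statistic in the permutation distribution
#' divided by the number of permutations: `p = #\{null >= observed\} / N`,
#' floored at `1/N`. Ties count against the observed value.
#'
#' @param observed observed statistic.
#' @param null vector of permuted statistics (NAs dropped).
#' @return p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(observed, null) {
  null <- null[!is.na(null)]
  if (!length(null)) stop("null distribution is empty")
  if (is.na(observed)) return(NA_real_)
  max(sum(null >= observed), 1L) / length(null)
}

#' Minimal permutation count for corrected significance
#'
#' The smallest `N` whose p-value floor `1/N` still allows detection at a
#' Bonferroni-adjusted level: smallest `N` with `1/N <= alpha / n_tests`.
#'
#' @param alpha significance level in (0, 1).
#' @param n_tests number of simultaneous tests (>= 1).
#' @return Integer `N`.
#' @examples
#' required_N(0.05, 1)    # 20
#' required_N(0.001, 1)   # 1000
#' required_N(0.05, 26)   # 520
#' @export
required_N <- function(alpha, n_tests = 1) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  as.integer(ceiling(n_tests / alpha - 1e-9))
}

# all distinct within-session label arrangements (columns) of y in {-1,+1}
enumerate_within_session <- function(y, sessions, max_enumerate = 1e5) {
  per <- lapply(unique(sessions), function(s) {
    idx <- which(sessions == s)
    npos <- sum(y[idx] > 0)
    pos_sets <- combn(length(idx), npos)
    list(idx = idx, pos_sets = pos_sets)
  })
  counts <- vapply(per, function(p) ncol(p$pos_sets), numeric(1))
  total <- prod(counts)
  if (total > max_enumerate)
    stop("too many within-session arrangements to enumerate (", total, ")")
  out <- matrix(-1L, length(y), total)
  reps <- 1
  for (p in per) {
    m <- ncol(p$pos_sets)
    block <- rep(rep(seq_len(m), each = reps), length.out = total)
    for (col in seq_len(total)) {
      ch <- p$pos_sets[, block[col]]
      out[p$idx[ch], col] <- 1L
    }
    reps <- reps * m
  }
  out
}

#' Permutation null of classifier weights
#'
#' Trains the classifier on all trials of a subject, then re-estimates it on
#' `N` within-session label permutations and summarizes the resulting
#' per-voxel weight distributions by their sample mean and standard
#' deviation. Raw draws are retained only on request (needed for the
#' normality audit); otherwise mean/SD are accumulated streaming.
#'
#' @param x trials-by-voxels feature matrix (scaled as for the observed
#'   fit).
#' @param labels observed labels (define the per-session label multisets).
#' @param sessions per-trial session index.
#' @param N number of permutations (ignored when `exhaustive`).
#' @param C regularization hyperparameter used for every refit.
#' @param seed optional seed.
#' @param keep_draws retain the `N x V` matrix of permuted weights.
#' @param exhaustive enumerate all distinct within-session arrangements
#'   instead of sampling (small instances only).
#' @param eps,max_iter solver controls.
#' @return Object of class `weight_null`: `mu`, `sd` (per voxel), `N`,
#'   `flagged` (voxels with zero null SD, where t is undefined), `draws`
#'   (or NULL), `C`.
#' @export
weight_null <- function(x, labels, sessions, N = 2000, C = 1, seed = NULL,
                        keep_draws = FALSE, exhaustive = FALSE,
                        eps = 1e-6, max_iter = 200000L) {
  y <- to_pm1(labels)
  K <- tcrossprod(x)
  V <- ncol(x)
  fit_w <- function(yk) {
    fit <- .cpp_smo(K, yk, C, eps, as.integer(max_iter))
    drop(crossprod(x, fit$alpha * yk))
  }
  if (exhaustive) {
    Ys <- enumerate_within_session(y, sessions)
    M <- ncol(Ys)
    draws <- matrix(NA_real_, M, V)
    for (k in seq_len(M)) draws[k, ] <- fit_w(Ys[, k])
  } else {
    stopifnot(N >= 1)
    M <- as.integer(N)
    draws <- with_seed(seed, {
      d <- matrix(NA_real_, M, V)
      for (k in seq_len(M)) {
        yk <- permute_within_sessions(y, sessions)
        d[k, ] <- fit_w(yk)
      }
      d
    })
  }
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, stats::sd)
  flagged <- which(sdv == 0 | !is.finite(sdv))
  structure(list(mu = mu, sd = sdv, N = M, flagged = flagged,
                 draws = if (keep_draws || exhaustive) draws, C = C),
            class = "weight_null")
}

#' t-scores of observed weights against their permutation nulls
#'
#' `t_v = (w_v - mu_v) / sd_v`, referred to Student's t distribution on
#' `N - 1` degrees of freedom (two-sided). Voxels with zero null SD are
#' excluded (NA) and counted.
#'
#' @param w observed weight vector (e.g. `train_linear_margin(...)$w`).
#' @param null a [weight_null()].
#' @param grid_shape optional 3D dimensions, enabling the random-field
#'   correction in [fwe_threshold()] and spatial output.
#' @return Object of class `weight_tmap`: `w`, `t`, `p`, `df`, `flagged`,
#'   `n_flagged`, `grid_shape`.
#' @export
weight_tscores <- function(w, null, grid_shape = NULL) {
  stopifnot(inherits(null, "weight_null"), length(w) == length(null$mu))
  t <- (w - null$mu) / null$sd
  if (length(null$flagged)) t[null$flagged] <- NA_real_
  df <- null$N - 1
  p <- 2 * pt(-abs(t), df = df)
  structure(list(w = w, t = t, p = p, df = df, flagged = null$flagged,
                 n_flagged = length(null$flagged), grid_shape = grid_shape),
            class = "weight_tmap")
}

#' Fraction of voxel nulls rejected by a normality test
#'
#' Audits the Gaussian summary of the weight nulls. The default method is
#' the Lilliefors-corrected Kolmogorov-Smirnov test, whose rejection rate
#' under Gaussian data equals the test size; the plug-in KS test against a
#' Gaussian with the same sample's estimated mean/SD (`"ks_plugin"`) is
#' available for comparison but is markedly conservative because the
#' parameters are fit to the tested sample. Degenerate (zero-variance)
#' nulls count as rejections.
#'
#' @param draws `N x V` matrix of raw permutation draws, or a
#'   [weight_null()] built with `keep_draws = TRUE`.
#' @param alpha test size.
#' @param method `"lilliefors"` or `"ks_plugin"`.
#' @return Fraction of voxels whose null is rejected as non-Gaussian.
#' @export
normality_fraction <- function(draws, alpha = 0.05,
                               method = c("lilliefors", "ks_plugin")) {
  method <- match.arg(method)
  if (inherits(draws, "weight_null")) {
    if (is.null(draws$draws))
      stop("weight_null was built without keep_draws = TRUE")
    draws <- draws$draws
  }
  rej <- vapply(seq_len(ncol(draws)), function(v) {
    x <- draws[, v]
    if (stats::sd(x) == 0) return(TRUE)
    p <- if (method == "lilliefors") nortest::lillie.test(x)$p.value
         else suppressWarnings(ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
    p < alpha
  }, logical(1))
  mean(rej)
}

# expected Euler characteristic densities of a t field (per resel dimension)
t_field_ec <- function(t, df) {
  a <- 4 * log(2)
  b <- exp(lgamma((df + 1) / 2) - lgamma(df / 2))
  cc <- (1 + t^2 / df)^((1 - df) / 2)
  c(pt(t, df, lower.tail = FALSE),
    sqrt(a) / (2 * pi) * cc,
    a / (2 * pi)^1.5 * cc * t * b / sqrt(df / 2),
    a^1.5 / (2 * pi)^2 * cc * ((df - 1) * t^2 / df - 1))
}

# per-axis smoothness (FWHM in voxels) of a standardized 3D field
estimate_fwhm_vox <- function(vol) {
  u <- (vol - mean(vol, na.rm = TRUE)) / stats::sd(vol, na.rm = TRUE)
  vapply(1:3, function(ax) {
    d <- apply(u, setdiff(1:3, ax), diff)
    lambda <- mean(d^2, na.rm = TRUE)
    if (!is.finite(lambda) || lambda <= 0) return(1)
    max(1, sqrt(4 * log(2) / lambda))
  }, numeric(1))
}

#' Family-wise error threshold for a weight t-map
#'
#' Bonferroni (default): each voxel tested at `alpha / V` on the two-sided
#' `t_(N-1)` p-value — deliberately conservative. Random-field theory
#' (`"rft"`): the two-sided expected-Euler-characteristic threshold for a t
#' field over the 3D search box, with per-axis smoothness estimated from
#' the map itself unless supplied.
#'
#' @param tmap a [weight_tscores()] result.
#' @param alpha family-wise level in (0, 1).
#' @param method `"bonferroni"` or `"rft"`.
#' @param fwhm_vox optional per-axis smoothness (voxels) for `"rft"`.
#' @return List with `method`, `threshold` (on |t|), `per_voxel_alpha`
#'   (Bonferroni only), `mask_pos` and `mask_neg` (significant voxels split
#'   by sign: positive = higher activity on painful trials), `alpha`.
#' @export
fwe_threshold <- function(tmap, alpha = 0.05,
                          method = c("bonferroni", "rft"), fwhm_vox = NULL) {
  stopifnot(inherits(tmap, "weight_tmap"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  method <- match.arg(method)
  scored <- !is.na(tmap$t)
  V <- sum(scored)
  if (method == "bonferroni") {
    level <- alpha / V
    thr <- qt(1 - level / 2, df = tmap$df)
    per_voxel_alpha <- level
  } else {
    if (is.null(tmap$grid_shape) || length(tmap$grid_shape) != 3)
      stop("random-field correction needs a 3D grid_shape on the t-map")
    if (is.null(fwhm_vox)) {
      vol <- array(tmap$t, dim = tmap$grid_shape)
      fwhm_vox <- estimate_fwhm_vox(vol)
    }
    dims <- (tmap$grid_shape - 1) / fwhm_vox
    resels <- c(1, sum(dims), dims[1] * dims[2] + dims[2] * dims[3] +
                  dims[1] * dims[3], prod(dims))
    target <- alpha / 2   # per tail
    f <- function(t) sum(resels * t_field_ec(t, tmap$df)) - target
    thr <- stats::uniroot(f, lower = 1e-3, upper = 100)$root
    per_voxel_alpha <- NA_real_
  }
  list(method = method, threshold = thr, per_voxel_alpha = per_voxel_alpha,
       mask_pos = which(scored & tmap$t >= thr),
       mask_neg = which(scored & tmap$t <= -thr),
       alpha = alpha)
}

#' Paired permutation comparison of two accuracy sets
#'
#' Sign-flip permutation test on per-subject accuracy differences: the
#' statistic is the mean difference, the null is generated by random (or
#' exhaustive) sign flips, and the two-sided p-value uses the same
#' tie-inclusive counting rule as [perm_pvalue()].
#'
#' @param a,b per-subject accuracies of the two analyses (same subjects,
#'   same order; >= 2 subjects).
#' @param N number of random sign-flip draws.
#' @param seed optional seed.
#' @param exact enumerate all `2^n` sign patterns (default when `2^n <= N`).
#' @return p-value in `(0, 1]`.
#' @export
paired_accuracy_comparison <- function(a, b, N = 1000, seed = NULL,
                                       exact = NULL) {
  if (length(a) != length(b)) stop("a and b must cover the same subjects")
  n <- length(a)
  if (n < 2) stop("need >= 2 subjects")
  d <- a - b
  obs <- abs(mean(d))
  exact <- exact %||% (2^n <= N)
  tol <- 1e-12
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- abs(as.vector(signs %*% d)) / n
    max(sum(null >= obs - tol), 1L) / length(null)
  } else {
    null <- with_seed(seed, vapply(seq_len(N), function(i)
      abs(mean(d * sample(c(-1, 1), n, replace = TRUE))), numeric(1)))
    max(sum(null >= obs - tol), 1L) / N
  }
}
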