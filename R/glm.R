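# Trial-wise first-level GLM: canonical HRF, per-trial anticipation and
# stimulation boxcar regressors sampled on a 0.1 s microtime grid, DCT
# high-pass filtering, pooled AR(1) prewhitening, and Gaussian smoothing.
# With T trials the design carries 2T trial regressors (240 for the standard
# 4 x 30 design) plus one constant per session.

#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: difference of two gamma densities with peak
#' delay 6 s, undershoot delay 16 s, unit dispersions and undershoot ratio
#' 1/6, supported on 0-32 s.
#'
#' @param TR sampling interval in seconds (> 0); also used as the microtime
#'   step when building designs.
#' @param duration kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay,peak_disp,undershoot_disp,ratio the
#'   fixed published parameterization.
#' @return Numeric vector of kernel values sampled at `seq(0, duration, by = TR)`.
#' @examples
#' h <- hrf_kernel(3)     # 11 samples on 0, 3, ..., 30 s
#' h[1]                   # 0 at t = 0
#' @export
hrf_kernel <- function(TR, duration = 32, peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  if (TR <= 0) stop("TR must be > 0")
  t <- seq(0, duration, by = TR)
  dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * dgamma(t, shape = undershoot_delay / undershoot_disp,
                   scale = undershoot_disp)
}

#' Build a trial-wise design matrix
#'
#' One anticipation boxcar (trial-specific duration) and one 1 s stimulation
#' boxcar per trial, each convolved with the canonical HRF on a fine
#' microtime grid and sampled at volume acquisition times (volume timing
#' referenced to slice-time 0), plus one constant column per session.
#' Regressors of different trials may overlap in time; that is what the
#' joint GLM disentangles.
#'
#' @param events a `pain_events` table (or a data frame with the same
#'   columns; may have zero rows for a constant-only design).
#' @param TR repetition time in seconds.
#' @param n_volumes integer vector of volumes per session; defaults to the
#'   session durations recorded on `events`.
#' @param microtime_dt microtime resolution in seconds.
#' @param hrf HRF kernel sampled at `microtime_dt` (defaults to
#'   [hrf_kernel()]).
#' @return An object of class `pain_design`: list with `X` (time x
#'   regressor), `names`, `kind` (per column: `trial_anticipation`,
#'   `trial_stimulation`, `constant`), `trial` (per column: global trial
#'   index or NA), `sessions` (per row), `trial_meta`, `TR`, `n_volumes`.
#' @export
build_trialwise_design <- function(events, TR = 3, n_volumes = NULL,
                                   microtime_dt = 0.1,
                                   hrf = hrf_kernel(microtime_dt)) {
  if (is.null(n_volumes)) {
    durations <- attr(events, "session_duration")
    if (is.null(durations)) stop("n_volumes not given and events carry no session_duration")
    n_volumes <- as.integer(ceiling(durations / TR))
  }
  n_sessions <- length(n_volumes)
  if (nrow(events) > 0 && max(events$session) > n_sessions)
    stop("events reference sessions beyond n_volumes")

  n_trials <- nrow(events)
  total_vols <- sum(n_volumes)
  X <- matrix(0, total_vols, 2L * n_trials + n_sessions)
  kind <- c(rep(c("trial_anticipation", "trial_stimulation"), n_trials),
            rep("constant", n_sessions))
  trial_of_col <- c(rep(seq_len(n_trials), each = 2), rep(NA_integer_, n_sessions))
  nm <- character(ncol(X))
  sessions_row <- rep(seq_len(n_sessions), n_volumes)
  row_offset <- c(0L, cumsum(n_volumes))

  for (s in seq_len(n_sessions)) {
    nv <- n_volumes[s]
    rows <- row_offset[s] + seq_len(nv)
    X[rows, 2L * n_trials + s] <- 1
    nm[2L * n_trials + s] <- sprintf("session%d_const", s)
    ev_s <- which(nrow(events) > 0 & events$session == s)
    if (!length(ev_s)) next
    scan_len <- nv * TR
    n_micro <- round(scan_len / microtime_dt)
    t_micro <- (seq_len(n_micro) - 1) * microtime_dt
    vol_idx <- round(((seq_len(nv) - 1) * TR) / microtime_dt) + 1L
    for (i in ev_s) {
      if (events$stimulation_onset[i] + events$stimulation_duration[i] > scan_len)
        stop(sprintf("trial %d of session %d extends beyond scan end", events$trial[i], s))
      g <- i  # events rows are in global trial order
      for (ph in 1:2) {
        onset <- if (ph == 1) events$anticipation_onset[i] else events$stimulation_onset[i]
        dur <- if (ph == 1) events$anticipation_duration[i] else events$stimulation_duration[i]
        u <- as.numeric(t_micro >= onset & t_micro < onset + dur)
        conv <- convolve(u, rev(hrf), type = "open")[seq_len(n_micro)] * microtime_dt
        X[rows, 2L * g - 2L + ph] <- conv[vol_idx]
        nm[2L * g - 2L + ph] <- sprintf("t%03d_%s", g, c("antic", "stim")[ph])
      }
    }
  }
  colnames(X) <- nm
  meta <- if (n_trials > 0)
    data.frame(session = events$session, trial = events$trial,
               label = events$label, threat = events$threat,
               stringsAsFactors = FALSE)
  else data.frame(session = integer(0), trial = integer(0),
                  label = character(0), threat = character(0))
  structure(list(X = X, names = nm, kind = kind, trial = trial_of_col,
                 sessions = sessions_row, trial_meta = meta, TR = TR,
                 n_volumes = n_volumes),
            class = "pain_design")
}

# orthonormal DCT basis including the constant term; order chosen so the
# slowest retained cosine has period >= cutoff
dct_basis <- function(n, TR, cutoff) {
  k <- floor(2 * (n * TR) / cutoff + 1)
  k <- max(1L, min(as.integer(k), n))
  t <- seq_len(n) - 1
  D <- matrix(1 / sqrt(n), n, k)
  if (k > 1)
    for (r in seq_len(k - 1))
      D[, r + 1] <- sqrt(2 / n) * cos(pi * (2 * t + 1) * r / (2 * n))
  D
}

#' High-pass filter by discrete-cosine projection
#'
#' Removes the session mean and all cosine components slower than
#' `cutoff_s` by projecting onto the orthogonal complement of a DCT basis,
#' the residual-forming projection used in standard first-level fMRI models.
#' The same projection must be applied to data and design (as [fit_glm()]
#' does) for estimates to be unaffected by the nuisance space.
#'
#' @param x numeric vector or time-by-series matrix.
#' @param TR sampling interval (s).
#' @param cutoff_s high-pass cutoff period in seconds (default 128; must
#'   exceed `2 * TR`).
#' @param sessions optional per-row session index; filtering is applied
#'   within each session block.
#' @return Filtered object of the same shape.
#' @export
highpass_dct <- function(x, TR, cutoff_s = 128, sessions = NULL) {
  if (cutoff_s <= 2 * TR) stop("cutoff_s must exceed 2 * TR")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(m) < 2) stop("need at least 2 time points")
  sessions <- sessions %||% rep(1L, nrow(m))
  for (s in unique(sessions)) {
    rows <- which(sessions == s)
    if (length(rows) < 2) stop("need at least 2 time points per session")
    D <- dct_basis(length(rows), TR, cutoff_s)
    m[rows, ] <- m[rows, , drop = FALSE] -
      D %*% crossprod(D, m[rows, , drop = FALSE])
  }
  if (vec) drop(m) else m
}

#' Estimate and invert first-order autoregressive noise
#'
#' Estimates a single lag-1 autocorrelation coefficient pooled over all
#' series (and sessions) from GLM residuals, and returns the corresponding
#' whitening transform: `x'_1 = sqrt(1 - rho^2) x_1`,
#' `x'_t = x_t - rho x_(t-1)` within each session. Estimates with
#' `|rho| >= 1` are clipped to +/- 0.95 with a warning.
#'
#' @param resid residual vector or time-by-series matrix (>= 10 time points).
#' @param sessions optional per-row session index.
#' @return List with `rho` and `whiten`, a function applying the transform
#'   to a vector or matrix of matching length.
#' @export
ar1_fit_whiten <- function(resid, sessions = NULL) {
  m <- if (is.null(dim(resid))) matrix(resid, ncol = 1) else resid
  if (nrow(m) < 10) stop("need >= 10 time points to estimate AR(1)")
  sessions <- sessions %||% rep(1L, nrow(m))
  num <- 0; den <- 0
  for (s in unique(sessions)) {
    rows <- which(sessions == s)
    r <- m[rows, , drop = FALSE]
    if (length(rows) >= 2)
      num <- num + sum(r[-1, , drop = FALSE] * r[-length(rows), , drop = FALSE])
    den <- den + sum(r * r)
  }
  rho <- if (den > 0) num / den else 0
  if (abs(rho) >= 1) {
    warning(sprintf("AR(1) estimate %.3f outside (-1,1); clipped to +/-0.95", rho))
    rho <- sign(rho) * 0.95
  }
  whiten <- local({
    rho_ <- rho
    sess_ <- sessions
    function(x) {
      vec <- is.null(dim(x))
      w <- if (vec) matrix(x, ncol = 1) else x
      if (nrow(w) != length(sess_)) stop("length mismatch with fitted sessions")
      if (rho_ != 0) {
        out <- w
        for (s in unique(sess_)) {
          rows <- which(sess_ == s)
          out[rows[1], ] <- sqrt(1 - rho_^2) * w[rows[1], ]
          if (length(rows) > 1)
            out[rows[-1], ] <- w[rows[-1], , drop = FALSE] -
              rho_ * w[rows[-length(rows)], , drop = FALSE]
        }
        w <- out
      }
      if (vec) drop(w) else w
    }
  })
  list(rho = rho, whiten = whiten)
}

#' Construct a beta series container
#'
#' Per-trial, per-phase voxel pattern matrices with aligned trial metadata;
#' the classifier's input. Usually produced by [fit_glm()] /
#' [estimate_beta_series()], but can be built directly from externally
#' estimated single-trial patterns.
#'
#' @param anticipation,stimulation trials-by-voxels matrices (finite values).
#' @param meta data frame with one row per trial: `session`, `trial`,
#'   `label`, `threat`.
#' @param grid_shape optional 3D grid dimensions the voxel columns index.
#' @param atlas optional `pain_atlas`.
#' @param subject_id optional identifier.
#' @param rho optional AR(1) estimate carried over from the GLM.
#' @return An object of class `beta_series`.
#' @export
beta_series <- function(anticipation, stimulation, meta, grid_shape = NULL,
                        atlas = NULL, subject_id = NULL, rho = NA_real_) {
  stopifnot(is.matrix(anticipation), is.matrix(stimulation),
            nrow(anticipation) == nrow(meta),
            nrow(stimulation) == nrow(meta),
            ncol(anticipation) == ncol(stimulation))
  if (!all(is.finite(anticipation)) || !all(is.finite(stimulation)))
    stop("beta patterns must be finite")
  structure(list(patterns = list(anticipation = anticipation,
                                 stimulation = stimulation),
                 meta = meta, grid_shape = grid_shape, atlas = atlas,
                 subject_id = subject_id, rho = rho),
            class = "beta_series")
}

#' Fit the trial-wise GLM
#'
#' Ordinary least squares after (optionally) projecting out the
#' discrete-cosine nuisance space from both data and design and prewhitening
#' both with a pooled AR(1) model estimated from first-pass residuals. The
#' per-trial anticipation and stimulation estimates are returned as a
#' [beta_series()].
#'
#' @param volumes 4D array (x,y,z,time) or time-by-voxel matrix.
#' @param design a `pain_design`.
#' @param highpass apply the 128 s DCT filter (the session constants are
#'   absorbed into the projected-out nuisance space).
#' @param cutoff_s high-pass cutoff (s).
#' @param ar1 estimate and apply AR(1) prewhitening.
#' @return A `beta_series`; the pooled AR(1) estimate is stored as `$rho`.
#' @export
fit_glm <- function(volumes, design, highpass = TRUE, cutoff_s = 128,
                    ar1 = TRUE) {
  stopifnot(inherits(design, "pain_design"))
  grid_shape <- NULL
  if (is.array(volumes) && length(dim(volumes)) == 4) {
    grid_shape <- dim(volumes)[1:3]
    volumes <- t(matrix(volumes, prod(grid_shape), dim(volumes)[4]))
  }
  Y <- as.matrix(volumes)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("time dimension of volumes does not match the design")
  kind <- design$kind
  sessions <- design$sessions

  if (highpass) {
    Y <- highpass_dct(Y, design$TR, cutoff_s, sessions)
    X <- highpass_dct(X, design$TR, cutoff_s, sessions)
    keep <- kind != "constant"   # constants lie in the projected-out space
    X <- X[, keep, drop = FALSE]
    kind <- kind[keep]
  }

  check_rank <- function(M) {
    q <- qr(M)
    if (q$rank < ncol(M)) {
      bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
      stop("design is rank deficient after filtering; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    q
  }
  q1 <- check_rank(X)
  beta <- qr.coef(q1, Y)
  if (ar1) {
    resid <- Y - X %*% beta
    w <- ar1_fit_whiten(resid, sessions)
    Y <- w$whiten(Y)
    X <- w$whiten(X)
    beta <- qr.coef(check_rank(X), Y)
    rho <- w$rho
  } else rho <- 0

  antic <- beta[kind == "trial_anticipation", , drop = FALSE]
  stim <- beta[kind == "trial_stimulation", , drop = FALSE]
  rownames(antic) <- rownames(stim) <- NULL
  beta_series(antic, stim, design$trial_meta, grid_shape = grid_shape,
              rho = rho)
}

#' Estimate a subject's beta series from simulated volumes
#'
#' Convenience wrapper: optional Gaussian smoothing, design construction
#' from the subject's events, and [fit_glm()].
#'
#' @param subject a `pain_subject`.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 = none).
#' @param highpass,cutoff_s,ar1 passed to [fit_glm()].
#' @return A `beta_series` carrying the subject's atlas and id.
#' @export
estimate_beta_series <- function(subject, fwhm_mm = 0, highpass = TRUE,
                                 cutoff_s = 128, ar1 = TRUE) {
  stopifnot(inherits(subject, "pain_subject"))
  vols <- subject$volumes
  if (fwhm_mm > 0)
    vols <- smooth_gaussian(vols, fwhm_mm, subject$atlas$voxel_size_mm)
  design <- build_trialwise_design(subject$events, TR = subject$TR,
                                   n_volumes = subject$session_n_volumes)
  bs <- fit_glm(vols, design, highpass = highpass, cutoff_s = cutoff_s,
                ar1 = ar1)
  bs$atlas <- subject$atlas
  bs$subject_id <- subject$subject_id
  bs$grid_shape <- subject$atlas$grid_shape
  bs
}

# zero-padded separable 1D convolution along one axis
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1) / 2
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1
    if (off >= 0) { dst <- seq_len(n - off) }
    else { dst <- seq(1 - off, n) }
    out[dst, ] <- out[dst, ] + k[j] * m[dst + off, , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Separable Gaussian smoothing
#'
#' Isotropic Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))`,
#' applied separably along the three spatial axes. Edges are renormalized so
#' a constant image passes through unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D array, or 4D array smoothed volume-by-volume.
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  nd <- length(dim(volume))
  if (nd == 4) {
    for (t in seq_len(dim(volume)[4]))
      volume[, , , t] <- smooth_gaussian(volume[, , , t], fwhm_mm, voxel_size_mm)
    return(volume)
  }
  if (nd != 3) stop("volume must be a 3D or 4D array")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- volume
  norm <- array(1, dim(volume))
  for (ax in 1:3) {
    out <- conv_axis(out, k, ax)
    norm <- conv_axis(norm, k, ax)
  }
  out / norm
}
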