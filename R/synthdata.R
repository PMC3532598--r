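# Synthetic multi-subject fMRI datasets with the statistical structure the
# decoding analysis assumes: session/trial structure with a crossed two-level
# threat factor, near-threshold perception labels, HRF-convolved trial
# responses, low-frequency drift and AR(1) noise, plus ground truth for
# recovery tests. Geometry is deliberately simple (rectangular-block atlas on
# a small grid): the statistics under test do not depend on it.

PAIN_REGION_NAMES <- c(
  "SI.L", "SI.R", "SII.L", "SII.R", "AI.L", "AI.R", "MI.L", "MI.R",
  "PI.L", "PI.R", "dACC", "rACC", "MCC", "DLPFC.L", "DLPFC.R",
  "VLPFC.L", "VLPFC.R", "OFC.L", "OFC.R", "AMYG.L", "AMYG.R",
  "THA.L", "THA.R", "PAG.L", "PAG.R", "SMA")

#' Generate a trial event table
#'
#' Builds the per-trial event structure of a near-threshold pain experiment:
#' `n_sessions` scanning sessions of `trials_per_session` trials each. Every
#' trial has an anticipation period of trial-specific duration (uniform on
#' `anticipation_range` seconds) followed immediately by a brief laser
#' stimulus, a perception label (`pain`/`no_pain`, drawn Bernoulli with
#' probability `label_balance` independently of everything else), and a
#' two-level threat condition balanced within each session.
#'
#' @param n_sessions number of sessions (>= 2; leave-one-session-out
#'   cross-validation is undefined otherwise). Default 4.
#' @param trials_per_session trials per session (>= 2). Default 30.
#' @param label_balance probability that a trial is perceived as painful.
#' @param anticipation_range range (s) of the uniform anticipation duration.
#' @param stim_duration laser stimulus duration (s).
#' @param iti_range range (s) of the uniform interval between stimulus offset
#'   and the next anticipation onset.
#' @param lead_in,washout dead time (s) at the start and end of each session.
#' @param seed optional integer seed; the global RNG stream is not disturbed.
#' @return A data frame of class `pain_events` with columns `session`,
#'   `trial`, `anticipation_onset`, `anticipation_duration`,
#'   `stimulation_onset`, `stimulation_duration`, `label`, `threat`; onsets
#'   are in seconds relative to session start. The per-session scan length
#'   (s) is stored in `attr(, "session_duration")`.
#' @examples
#' ev <- generate_events(n_sessions = 4, trials_per_session = 30, seed = 1)
#' nrow(ev)            # 120 trials
#' table(ev$session)   # 30 per session
#' @export
generate_events <- function(n_sessions = 4, trials_per_session = 30,
                            label_balance = 0.5,
                            anticipation_range = c(4, 8), stim_duration = 1,
                            iti_range = c(6, 10), lead_in = 10, washout = 12,
                            seed = NULL) {
  if (n_sessions < 2)
    stop("need >= 2 sessions (leave-one-session-out is undefined for fewer)")
  if (trials_per_session < 2) stop("need >= 2 trials per session")
  if (label_balance < 0 || label_balance > 1)
    stop("label_balance must lie in [0, 1]")
  with_seed(seed, {
    rows <- vector("list", n_sessions)
    durations <- numeric(n_sessions)
    for (s in seq_len(n_sessions)) {
      n <- trials_per_session
      threat <- sample(rep_len(c("high", "low"), n))
      label <- ifelse(runif(n) < label_balance, "pain", "no_pain")
      antic_dur <- runif(n, anticipation_range[1], anticipation_range[2])
      iti <- runif(n, iti_range[1], iti_range[2])
      onset <- numeric(n)
      t <- lead_in
      for (i in seq_len(n)) {
        onset[i] <- t
        t <- t + antic_dur[i] + stim_duration + iti[i]
      }
      durations[s] <- onset[n] + antic_dur[n] + stim_duration + washout
      rows[[s]] <- data.frame(
        session = s, trial = seq_len(n),
        anticipation_onset = onset, anticipation_duration = antic_dur,
        stimulation_onset = onset + antic_dur,
        stimulation_duration = stim_duration,
        label = label, threat = threat, stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
    attr(ev, "session_duration") <- durations
    class(ev) <- c("pain_events", "data.frame")
    ev
  })
}

#' Generate a block atlas of pain-related regions
#'
#' Places `n_regions + n_control` disjoint cubic regions of side
#' `region_size` voxels on a regular lattice inside `grid_shape`. With the
#' default 26 regions the names follow the conventional pain-matrix
#' nomenclature (SI/SII, insula subdivisions, cingulate, prefrontal, OFC,
#' amygdala, thalamus, PAG, SMA); control regions default to bilateral
#' Heschl's gyrus (`HG.L`, `HG.R`), which carries no planted signal.
#'
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param n_regions number of pain-related regions (default 26).
#' @param n_control number of control regions (default 2).
#' @param region_size cube side length in voxels.
#' @param voxel_size_mm isotropic voxel size, used by smoothing and NIfTI
#'   headers.
#' @param seed optional seed controlling the (shuffled) assignment of regions
#'   to lattice slots.
#' @return An object of class `pain_atlas`: list with `labels` (3D integer
#'   array, 0 = background, k = region k), `region_names`, `control_regions`,
#'   `grid_shape`, `voxel_size_mm`.
#' @export
generate_atlas <- function(grid_shape = c(24, 24, 24), n_regions = 26,
                           n_control = 2, region_size = 3, voxel_size_mm = 3,
                           seed = NULL) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= region_size))
  n_total <- n_regions + n_control
  if (n_total < 1) stop("need at least one region")
  step <- region_size + 1
  starts <- lapply(grid_shape, function(g) seq(1, g - region_size + 1, by = step))
  slots <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  if (nrow(slots) < n_total)
    stop(sprintf("cannot pack %d regions of size %d into grid %s",
                 n_total, region_size, paste(grid_shape, collapse = "x")))
  slot_order <- with_seed(seed, sample.int(nrow(slots)))[seq_len(n_total)]

  region_names <- if (n_regions == 26) PAIN_REGION_NAMES
                  else sprintf("R%02d", seq_len(n_regions))
  control_names <- if (n_control == 2) c("HG.L", "HG.R")
                   else if (n_control > 0) sprintf("CTRL%d", seq_len(n_control))
                   else character(0)
  all_names <- c(region_names, control_names)

  labels <- array(0L, dim = grid_shape)
  off <- seq_len(region_size) - 1L
  for (k in seq_len(n_total)) {
    s <- slots[slot_order[k], ]
    labels[s$x + off, s$y + off, s$z + off] <- k
  }
  structure(list(labels = labels, region_names = all_names,
                 control_regions = control_names, grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm),
            class = "pain_atlas")
}

#' Linear voxel indices of a set of atlas regions
#'
#' @param atlas a `pain_atlas`.
#' @param regions character vector of region names; `NULL` selects all
#'   regions (including controls).
#' @return Sorted integer vector of linear indices into the 3D grid.
#' @export
region_voxels <- function(atlas, regions = NULL) {
  stopifnot(inherits(atlas, "pain_atlas"))
  regions <- regions %||% atlas$region_names
  miss <- setdiff(regions, atlas$region_names)
  if (length(miss)) stop("unknown regions: ", paste(miss, collapse = ", "))
  ids <- match(regions, atlas$region_names)
  idx <- which(atlas$labels %in% ids)
  if (!length(idx)) stop("region union is empty")
  sort(idx)
}

#' Specify the planted class signal of a synthetic subject
#'
#' Describes the weak distributed signal the generator plants: trials
#' perceived as painful get a higher response amplitude than non-painful
#' trials in the voxels of the named `regions`, during the named `phase`.
#' All atlas voxels respond to every trial with a common baseline amplitude;
#' the label effect is what the decoder has to find. The per-subject effect
#' size is drawn once per subject from Normal(`effect_size_mean`,
#' `effect_size_sd`), truncated at zero, inducing the random-effects
#' structure the group permutation test assumes.
#'
#' @param atlas a `pain_atlas`; informative regions must not be controls.
#' @param regions character vector of informative region names (may be empty
#'   for a null signal).
#' @param effect_size_mean,effect_size_sd group mean and between-subject SD
#'   of the pain-vs-no-pain amplitude difference (arbitrary units; all
#'   downstream steps are scale-invariant after standardization/l2 scaling).
#' @param phase which trial phase carries the effect:
#'   `"stimulation"`, `"anticipation"`, or `"both"`.
#' @param noise_sd marginal SD of the stationary AR(1) noise (> 0).
#' @param ar1_rho lag-1 autocorrelation of the noise, in (-1, 1).
#' @param drift_amplitude amplitude of the low-frequency scanner drift.
#' @param base_amplitude stimulus response amplitude common to all atlas
#'   voxels and both classes.
#' @return An object of class `pain_signal_spec`.
#' @export
signal_spec <- function(atlas, regions = character(0), effect_size_mean = 0,
                        effect_size_sd = 0,
                        phase = c("stimulation", "anticipation", "both"),
                        noise_sd = 1, ar1_rho = 0.3, drift_amplitude = 1,
                        base_amplitude = 1) {
  stopifnot(inherits(atlas, "pain_atlas"))
  phase <- match.arg(phase)
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)")
  bad <- intersect(regions, atlas$control_regions)
  if (length(bad))
    stop("informative regions must not be controls: ", paste(bad, collapse = ", "))
  mask <- array(FALSE, dim = atlas$grid_shape)
  if (length(regions)) mask[region_voxels(atlas, regions)] <- TRUE
  structure(list(informative_regions = regions, informative_voxel_mask = mask,
                 effect_size_mean = effect_size_mean,
                 effect_size_sd = effect_size_sd, phase = phase,
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 base_amplitude = base_amplitude),
            class = "pain_signal_spec")
}

# stationary AR(1) noise, one session block; marginal sd = noise_sd
ar1_noise <- function(n_time, n_voxels, rho, noise_sd) {
  x <- matrix(rnorm(n_time * n_voxels, sd = noise_sd * sqrt(1 - rho^2)),
              n_time, n_voxels)
  x[1, ] <- rnorm(n_voxels, sd = noise_sd)
  if (rho != 0 && n_time > 1)
    for (t in 2:n_time) x[t, ] <- rho * x[t - 1, ] + x[t, ]
  x
}

#' Simulate one subject's 4D volume series
#'
#' Voxel time series are the sum of (i) HRF-convolved boxcar responses to
#' every trial's anticipation and stimulation period, with amplitudes that
#' differ by perception label in the informative voxels only; (ii) a slow
#' cosine drift (period 192-384 s, so the 128 s high-pass filter has work to
#' do); and (iii) stationary AR(1) noise. Sessions are generated
#' independently and concatenated along the time axis.
#'
#' @param events a `pain_events` table.
#' @param atlas a `pain_atlas`.
#' @param signal a `pain_signal_spec`.
#' @param TR repetition time in seconds (default 3).
#' @param seed optional integer seed; identical seeds reproduce the dataset
#'   bit for bit.
#' @param subject_id identifier stamped on the dataset.
#' @return An object of class `pain_subject`: list with `volumes` (4D array
#'   x,y,z,time), `TR`, `events`, `atlas`, `truth` (signal spec plus the
#'   realized per-subject `effect_size`), `subject_id`, `seed`,
#'   `session_n_volumes`.
#' @export
simulate_subject <- function(events, atlas, signal, TR = 3, seed = NULL,
                             subject_id = "sub01") {
  stopifnot(inherits(events, "pain_events"), inherits(atlas, "pain_atlas"),
            inherits(signal, "pain_signal_spec"))
  durations <- attr(events, "session_duration")
  n_vols <- as.integer(ceiling(durations / TR))
  grid <- atlas$grid_shape
  V <- prod(grid)
  with_seed(seed, {
    # one effect size per subject, truncated-normal at zero
    delta <- if (signal$effect_size_sd == 0) signal$effect_size_mean else {
      d <- rnorm(1, signal$effect_size_mean, signal$effect_size_sd)
      tries <- 0
      while (d < 0 && tries < 1000) {
        d <- rnorm(1, signal$effect_size_mean, signal$effect_size_sd)
        tries <- tries + 1
      }
      max(d, 0)
    }

    design <- build_trialwise_design(events, TR = TR, n_volumes = n_vols)
    trial_cols <- design$kind != "constant"
    X <- design$X[, trial_cols, drop = FALSE]
    kind <- design$kind[trial_cols]
    trial_of_col <- design$trial[trial_cols]

    # per-regressor, per-voxel amplitudes
    in_atlas <- which(atlas$labels > 0)
    informative <- which(signal$informative_voxel_mask)
    A <- matrix(0, ncol(X), V)
    A[, in_atlas] <- signal$base_amplitude
    if (length(informative) && delta != 0) {
      eff_phase <- switch(signal$phase,
        stimulation = "trial_stimulation",
        anticipation = "trial_anticipation",
        both = c("trial_anticipation", "trial_stimulation"))
      lab_sign <- ifelse(events$label == "pain", 0.5, -0.5)
      hit <- kind %in% eff_phase
      A[hit, informative] <- A[hit, informative] +
        delta * lab_sign[trial_of_col[hit]]
    }
    Y <- X %*% A

    # drift + noise, per session
    row0 <- 0L
    for (s in seq_along(n_vols)) {
      nv <- n_vols[s]
      rows <- row0 + seq_len(nv)
      if (signal$drift_amplitude != 0) {
        period <- runif(1, 192, 384)
        phase0 <- runif(1, 0, 2 * pi)
        dt <- signal$drift_amplitude *
          cos(2 * pi * (seq_len(nv) - 1) * TR / period + phase0)
        w <- runif(V, 0.5, 1.5)
        Y[rows, ] <- Y[rows, ] + outer(dt, w)
      }
      Y[rows, ] <- Y[rows, ] +
        ar1_noise(nv, V, signal$ar1_rho, signal$noise_sd)
      row0 <- row0 + nv
    }

    truth <- signal
    truth$effect_size <- delta
    structure(list(volumes = array(t(Y), dim = c(grid, sum(n_vols))),
                   TR = TR, events = events, atlas = atlas, truth = truth,
                   subject_id = subject_id, seed = seed,
                   session_n_volumes = n_vols),
              class = "pain_subject")
  })
}

#' Generate a group of synthetic subjects
#'
#' Subjects share the atlas and signal specification but have independent
#' event randomizations, effect sizes and noise, all derived from a single
#' master seed (the same master seed reproduces the whole group bit for bit).
#'
#' @param n_subjects number of subjects (>= 2; default 16).
#' @param atlas shared `pain_atlas`.
#' @param signal shared `pain_signal_spec` (per-subject effect sizes are
#'   drawn inside [simulate_subject()]).
#' @param n_sessions,trials_per_session,label_balance passed to
#'   [generate_events()] per subject.
#' @param TR repetition time (s).
#' @param seed master seed.
#' @return An object of class `pain_group`: list with `subjects` (list of
#'   `pain_subject`), `atlas`, `seed`.
#' @export
generate_group <- function(n_subjects = 16, atlas, signal,
                           n_sessions = 4, trials_per_session = 30,
                           label_balance = 0.5, TR = 3, seed = NULL) {
  if (n_subjects < 2) stop("need >= 2 subjects")
  seeds <- derive_seeds(seed, 2L * n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ev <- generate_events(n_sessions, trials_per_session, label_balance,
                          seed = seeds[[2 * i - 1]])
    subjects[[i]] <- simulate_subject(ev, atlas, signal, TR = TR,
                                      seed = seeds[[2 * i]],
                                      subject_id = sprintf("sub%02d", i))
  }
  structure(list(subjects = subjects, atlas = atlas, seed = seed),
            class = "pain_group")
}
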