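# End-to-end study composition: simulate -> trial-wise GLM -> decode
# (whole brain, per ROI, cumulative combinations, voxel curve) ->
# permutation inference -> weight maps -> result tables and manifest.

#' Study configuration
#'
#' All analysis constants live here, never hard-coded in the pipeline: TR
#' 3 s, 128 s high-pass cutoff, 4 sessions x 30 trials, 16 subjects, 26 + 2
#' regions, permutation counts 1000 (accuracy) / 2600 (ROI analyses with
#' their 26-fold correction) / 2000 (weight maps), alpha 0.05. Override any
#' of them for desk-scale runs.
#'
#' @param n_subjects,n_sessions,trials_per_session,label_balance group and
#'   session structure.
#' @param TR repetition time (s).
#' @param grid_shape,n_regions,n_control,region_size,voxel_size_mm atlas
#'   geometry.
#' @param informative_regions regions carrying the planted signal.
#' @param effect_size_mean,effect_size_sd,signal_phase,noise_sd,ar1_rho,drift_amplitude
#'   signal/noise parameters (see [signal_spec()]).
#' @param fwhm_mm smoothing applied before the GLM (0 = none).
#' @param cutoff_s,ar1 GLM filtering options.
#' @param C_grid,scaling decoding options (see [decoding_config()]).
#' @param N_perm_accuracy,N_perm_roi,N_perm_weight permutation counts.
#' @param alpha significance level.
#' @param phases which trial phases to analyse.
#' @param combination_ks union sizes for the cumulative-ROI analysis.
#' @param seed master seed for the whole study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 16, n_sessions = 4,
                         trials_per_session = 30, label_balance = 0.5,
                         TR = 3, grid_shape = c(24, 24, 24), n_regions = 26,
                         n_control = 2, region_size = 3, voxel_size_mm = 3,
                         informative_regions = c("SI.L", "SI.R", "AI.R",
                                                 "SII.R", "OFC.R"),
                         effect_size_mean = 2, effect_size_sd = 0.8,
                         signal_phase = "stimulation", noise_sd = 1,
                         ar1_rho = 0.3, drift_amplitude = 1, fwhm_mm = 0,
                         cutoff_s = 128, ar1 = TRUE, C_grid = 10^(-3:3),
                         scaling = "fold", N_perm_accuracy = 1000,
                         N_perm_roi = 2600, N_perm_weight = 2000,
                         alpha = 0.05,
                         phases = c("anticipation", "stimulation"),
                         combination_ks = 1:5, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Simulate a group and estimate its beta series
#'
#' Streams subject by subject (volumes are discarded once the GLM has run)
#' so that group-level studies stay within desk-scale memory.
#'
#' @param config a [study_config()].
#' @param atlas optional pre-built atlas (default: built from the config).
#' @param progress print per-subject progress.
#' @return List with `betas` (list of `beta_series`), `atlas`, `signal`.
#' @export
simulate_group_betas <- function(config = study_config(), atlas = NULL,
                                 progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$seed, 2L * config$n_subjects + 1L)
  atlas <- atlas %||% generate_atlas(config$grid_shape, config$n_regions,
                                     config$n_control, config$region_size,
                                     config$voxel_size_mm,
                                     seed = seeds[[2L * config$n_subjects + 1L]])
  signal <- signal_spec(atlas, config$informative_regions,
                        config$effect_size_mean, config$effect_size_sd,
                        config$signal_phase, config$noise_sd,
                        config$ar1_rho, config$drift_amplitude)
  betas <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    if (progress) message("subject ", i, "/", config$n_subjects)
    ev <- generate_events(config$n_sessions, config$trials_per_session,
                          config$label_balance, seed = seeds[[2 * i - 1]])
    subj <- simulate_subject(ev, atlas, signal, TR = config$TR,
                             seed = seeds[[2 * i]],
                             subject_id = sprintf("sub%02d", i))
    betas[[i]] <- estimate_beta_series(subj, fwhm_mm = config$fwhm_mm,
                                       cutoff_s = config$cutoff_s,
                                       ar1 = config$ar1)
    rm(subj)
  }
  list(betas = betas, atlas = atlas, signal = signal)
}

#' Run the full study
#'
#' Composition: simulate and estimate beta series; whole-brain decoding with
#' group permutation inference; per-region decoding, significance ranking
#' and cumulative combinations of the most predictive regions; the
#' voxel-count scale curve; per-subject weight maps with FWE thresholds and
#' their across-subject mean. Stage outputs are written as TSV/JSON/NIfTI
#' under `out_dir` and reloaded instead of recomputed when present
#' (`overwrite = FALSE`), making runs resumable; a manifest records the
#' configuration and seed, from which the entire study is a pure function.
#'
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @param overwrite recompute stages whose outputs exist.
#' @param progress print stage progress.
#' @return Invisibly, a list with the result tables (`whole_brain`,
#'   `regions`, `combinations`, `scale_curve`, `weight_maps`).
#' @export
run_full_study <- function(config = study_config(), out_dir,
                           overwrite = FALSE, progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (progress) message(...)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", row.names = FALSE,
                                        quote = FALSE)
  stage_done <- function(name) !overwrite && file.exists(file.path(out_dir, name))

  write_manifest(run_manifest(unclass(config), config$seed),
                 file.path(out_dir, "manifest.json"))
  dcfg <- decoding_config(config$C_grid, config$scaling,
                          seed = config$seed)
  seeds <- derive_seeds(config$seed + 1L, 6L)

  # --- stage 1: synthesis + GLM ---------------------------------------
  beta_dir <- file.path(out_dir, "betas")
  if (!overwrite && dir.exists(beta_dir) &&
      length(list.dirs(beta_dir, recursive = FALSE)) == config$n_subjects) {
    say("stage 1: loading beta series")
    sub_dirs <- list.dirs(beta_dir, recursive = FALSE)
    betas <- lapply(sort(sub_dirs), read_beta_series)
  } else {
    say("stage 1: simulating group and fitting trial-wise GLMs")
    sim <- simulate_group_betas(config, progress = progress)
    betas <- sim$betas
    for (b in betas) write_beta_series(b, file.path(beta_dir, b$subject_id))
  }

  results <- list()

  # --- stage 2: whole-brain decoding ----------------------------------
  if (stage_done("whole_brain.tsv")) {
    say("stage 2: loading whole-brain results")
    results$whole_brain <- read.table(file.path(out_dir, "whole_brain.tsv"),
                                      sep = "\t", header = TRUE)
  } else {
    say("stage 2: whole-brain decoding")
    wb <- lapply(config$phases, function(ph) {
      g <- decode_group(betas, ph, feature_spec("whole_brain"), dcfg,
                        N_perm = config$N_perm_accuracy, seed = seeds[[1]])
      data.frame(phase = ph, features = "whole_brain",
                 accuracy = g$mean_accuracy, sem = g$sem, p = g$p,
                 N_perm = config$N_perm_accuracy)
    })
    results$whole_brain <- do.call(rbind, wb)
    tsv(results$whole_brain, "whole_brain.tsv")
  }

  # --- stage 3: per-region decoding + ranking + combinations ----------
  if (stage_done("regions.tsv") && stage_done("combinations.tsv")) {
    say("stage 3: loading region results")
    results$regions <- read.table(file.path(out_dir, "regions.tsv"),
                                  sep = "\t", header = TRUE)
    results$combinations <- read.table(file.path(out_dir, "combinations.tsv"),
                                       sep = "\t", header = TRUE)
  } else {
    say("stage 3: region-of-interest decoding")
    reg_list <- list(); comb_list <- list()
    for (ph in config$phases) {
      reg <- decode_regions(betas, ph, config = dcfg,
                            N_perm = config$N_perm_roi, seed = seeds[[2]])
      rk <- roi_rank_order(reg, config$alpha)
      rk$phase <- ph
      reg_list[[ph]] <- rk
      specs <- cumulative_roi_combinations(
        rk, ks = config$combination_ks[config$combination_ks <= nrow(rk)])
      cseeds <- derive_seeds(seeds[[3]], length(specs))
      comb <- do.call(rbind, lapply(seq_along(specs), function(i) {
        g <- decode_group(betas, ph, specs[[i]], dcfg,
                          N_perm = config$N_perm_accuracy, seed = cseeds[[i]])
        data.frame(phase = ph, combination = names(specs)[i],
                   features = format(specs[[i]]), accuracy = g$mean_accuracy,
                   sem = g$sem, p = g$p)
      }))
      comb_list[[ph]] <- comb
    }
    results$regions <- do.call(rbind, lapply(reg_list, as.data.frame))
    results$combinations <- do.call(rbind, comb_list)
    rownames(results$regions) <- rownames(results$combinations) <- NULL
    tsv(results$regions, "regions.tsv")
    tsv(results$combinations, "combinations.tsv")
  }

  # --- stage 4: voxel-count scale curve -------------------------------
  if (stage_done("scale_curve.tsv")) {
    say("stage 4: loading scale curve")
    results$scale_curve <- read.table(file.path(out_dir, "scale_curve.tsv"),
                                      sep = "\t", header = TRUE)
  } else {
    say("stage 4: voxel-count scale curve")
    sc <- lapply(config$phases, function(ph) {
      cur <- scale_curve(betas, ph, dcfg, N_perm = config$N_perm_accuracy,
                         seed = seeds[[4]])
      cur$phase <- ph
      as.data.frame(cur)
    })
    results$scale_curve <- do.call(rbind, sc)
    tsv(results$scale_curve, "scale_curve.tsv")
  }

  # --- stage 5: weight maps -------------------------------------------
  if (stage_done("weight_maps.tsv")) {
    say("stage 5: loading weight-map summary")
    results$weight_maps <- read.table(file.path(out_dir, "weight_maps.tsv"),
                                      sep = "\t", header = TRUE)
  } else {
    say("stage 5: weight-map inference")
    wseeds <- derive_seeds(seeds[[5]], length(betas) * length(config$phases))
    rows <- list(); si <- 0
    for (ph in config$phases) {
      maps <- lapply(seq_along(betas), function(i) {
        weight_map_analysis(betas[[i]], ph, N = config$N_perm_weight,
                            config = dcfg, alpha = config$alpha,
                            seed = wseeds[[si + i]])
      })
      si <- si + length(betas)
      grid <- betas[[1]]$grid_shape
      mean_t <- group_mean_tmap(maps)
      vol <- array(NA_real_, grid)
      vol[maps[[1]]$voxels] <- mean_t
      write_volume(vol, file.path(out_dir, paste0("mean_tmap_", ph, ".nii.gz")),
                   config$voxel_size_mm)
      rows[[ph]] <- do.call(rbind, lapply(maps, function(m)
        data.frame(phase = ph, subject = m$subject_id, C = m$C,
                   n_pos = length(m$fwe$mask_pos),
                   n_neg = length(m$fwe$mask_neg),
                   threshold = m$fwe$threshold,
                   n_flagged = m$tmap$n_flagged)))
    }
    results$weight_maps <- do.call(rbind, rows)
    rownames(results$weight_maps) <- NULL
    tsv(results$weight_maps, "weight_maps.tsv")
  }

  say("done: ", out_dir)
  invisible(results)
}
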