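# Whole-brain weight-map inference for one subject: train the classifier on
# all trials, relate each voxel's weight to its permutation null, and
# threshold the resulting t-map with a family-wise error correction.

#' Weight-map inference for one subject
#'
#' Trains the linear classifier once on all trials (whole-brain features,
#' standardized across all trials and l2-scaled per trial — this analysis is
#' not cross-validated), builds per-voxel permutation nulls of the weights
#' with within-session label shuffles, converts the observed weights to
#' t-scores on `N - 1` degrees of freedom, and applies the requested
#' family-wise error correction. Positive significant voxels are those whose
#' activity is higher on subjectively painful trials.
#'
#' @param beta a `beta_series`.
#' @param phase `"stimulation"` or `"anticipation"`.
#' @param N number of weight permutations.
#' @param C regularization hyperparameter; `NULL` selects it by
#'   leave-one-trial-out cross-validation on all trials.
#' @param config a [decoding_config()] (supplies the C grid and solver
#'   controls).
#' @param alpha family-wise error level.
#' @param correction `"bonferroni"` or `"rft"`.
#' @param seed permutation seed.
#' @param keep_draws retain raw permutation draws (enables
#'   [normality_fraction()]).
#' @return Object of class `weight_map_result`: the observed `fit`, the
#'   `null`, the `tmap`, the `fwe` threshold/masks, the grid `voxels` the
#'   features map to, and `C`.
#' @export
weight_map_analysis <- function(beta, phase = c("stimulation", "anticipation"),
                                N = 2000, C = NULL,
                                config = decoding_config(), alpha = 0.05,
                                correction = "bonferroni", seed = NULL,
                                keep_draws = FALSE) {
  stopifnot(inherits(beta, "beta_series"))
  phase <- match.arg(phase)
  X <- beta$patterns[[phase]]
  cols <- feature_columns(feature_spec("whole_brain"), beta$atlas, ncol(X))
  x <- l2_safe(standardize_voxels(X[, cols, drop = FALSE])$values)
  labels <- beta$meta$label
  sessions <- beta$meta$session
  if (is.null(C))
    C <- nested_select_C(x, labels, config$C_grid, config$eps,
                         config$max_iter)$C
  fit <- train_linear_margin(x, labels, C, config$eps, config$max_iter)
  null <- weight_null(x, labels, sessions, N = N, C = C, seed = seed,
                      keep_draws = keep_draws, eps = config$eps,
                      max_iter = config$max_iter)
  tmap <- weight_tscores(fit$w, null, grid_shape = beta$grid_shape)
  fwe <- fwe_threshold(tmap, alpha = alpha, method = correction)
  structure(list(fit = fit, null = null, tmap = tmap, fwe = fwe,
                 voxels = cols, phase = phase, C = C,
                 subject_id = beta$subject_id),
            class = "weight_map_result")
}

#' Across-subject mean of weight t-maps
#'
#' A simple voxel-wise mean of per-subject t-scores for visualization.
#' This is an interpretation aid, not a calibrated group statistic: the
#' permutation nulls are subject-specific.
#'
#' @param maps list of `weight_map_result` (same feature space).
#' @return Numeric vector of mean t-scores (NA where any subject is
#'   flagged).
#' @export
group_mean_tmap <- function(maps) {
  ts <- vapply(maps, function(m) m$tmap$t, numeric(length(maps[[1]]$tmap$t)))
  rowMeans(ts)
}
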