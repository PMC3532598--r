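utils::globalVariables(c("n_features", "accuracy", "sem", "scale_kind"))

# The spatial-scale study: per-region group decoding, ranking of regions by
# the significance of their accuracies, cumulative unions of the most
# predictive regions, the tripling voxel-count curve, and paired statistical
# comparison between scales.

#' Group decoding per region of interest
#'
#' Runs the full group decoding analysis independently on every region and
#' attaches a group permutation p-value per region.
#'
#' @param betas list of `beta_series` (shared atlas).
#' @param phase `"stimulation"` or `"anticipation"`.
#' @param regions region names (default: all atlas regions, controls
#'   included — controls belong in the ranking as negative checks).
#' @param config a [decoding_config()].
#' @param N_perm group permutations per region (e.g. `required_N(alpha,
#'   n_regions)` for Bonferroni-detectable significance).
#' @param seed master seed; per-region permutation seeds are derived from it.
#' @return Data frame of class `region_decoding` with columns `region`,
#'   `n_voxels`, `accuracy`, `sem`, `p`; the per-subject accuracy matrix is
#'   kept in `attr(, "subject_acc")`.
#' @export
decode_regions <- function(betas, phase = c("stimulation", "anticipation"),
                           regions = NULL, config = decoding_config(),
                           N_perm = 0, seed = NULL) {
  phase <- match.arg(phase)
  atlas <- betas[[1]]$atlas
  if (is.null(atlas)) stop("beta series carry no atlas")
  regions <- regions %||% atlas$region_names
  seeds <- derive_seeds(seed, length(regions))
  acc_mat <- matrix(NA_real_, length(betas), length(regions),
                    dimnames = list(NULL, regions))
  out <- data.frame(region = regions,
                    n_voxels = vapply(regions, function(r)
                      length(region_voxels(atlas, r)), numeric(1)),
                    accuracy = NA_real_, sem = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    g <- decode_group(betas, phase, feature_spec("roi", regions[i]),
                      config, N_perm = N_perm, seed = seeds[[i]])
    acc_mat[, i] <- g$subject_accuracies
    out$accuracy[i] <- g$mean_accuracy
    out$sem[i] <- g$sem
    out$p[i] <- g$p
  }
  attr(out, "subject_acc") <- acc_mat
  attr(out, "phase") <- phase
  class(out) <- c("region_decoding", "data.frame")
  out
}

#' Rank regions by the significance of their accuracies
#'
#' Sorts by permutation p-value ascending (significance, not magnitude —
#' the ranking accounts for between-subject variability); ties break by
#' higher mean accuracy, then region name. Significance flags use the
#' Bonferroni-corrected level `alpha / n_regions`.
#'
#' @param results a `region_decoding` data frame (columns `region`,
#'   `accuracy`, `p`; `sem`, `n_voxels` carried through if present).
#' @param alpha family-wise level.
#' @return The reordered data frame, class `roi_ranking`, with added
#'   columns `rank` and `significant`.
#' @export
roi_rank_order <- function(results, alpha = 0.05) {
  stopifnot(all(c("region", "accuracy", "p") %in% names(results)))
  n <- nrow(results)
  ord <- order(results$p, -results$accuracy, results$region)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$significant <- out$p <= alpha / n
  sa <- attr(results, "subject_acc")
  if (!is.null(sa)) attr(out, "subject_acc") <- sa[, ord, drop = FALSE]
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  class(out) <- c("roi_ranking", "data.frame")
  out
}

#' Cumulative combinations of the most predictive regions
#'
#' Feature specs for the union of the top-k ranked regions, plus the named
#' presets `pain_matrix` (all non-control regions) and `whole_brain`.
#'
#' @param ranking a [roi_rank_order()] result.
#' @param ks union sizes (default 1 up to the number of ranked regions).
#' @return Named list of [feature_spec()] objects
#'   (`top1`, `top2`, ..., `pain_matrix`, `whole_brain`).
#' @export
cumulative_roi_combinations <- function(ranking, ks = NULL) {
  stopifnot(inherits(ranking, "roi_ranking"))
  ks <- ks %||% seq_len(nrow(ranking))
  if (any(ks < 1 | ks > nrow(ranking))) stop("ks out of range")
  specs <- lapply(ks, function(k) {
    regs <- ranking$region[seq_len(k)]
    if (k == 1) feature_spec("roi", regs) else feature_spec("roi_union", regs)
  })
  names(specs) <- paste0("top", ks)
  c(specs, list(pain_matrix = feature_spec("pain_matrix"),
                whole_brain = feature_spec("whole_brain")))
}

#' Accuracy as a function of spatial scale
#'
#' The voxel-count curve: decoding from the `k` most discriminative voxels
#' for `k = 1, 3, 9, ...` (ranked by |t| within each training fold) up to
#' the whole brain, which is always included as an explicit final point.
#' Optionally merges per-region results onto the voxel-count axis via each
#' region's mask size.
#'
#' @param betas list of `beta_series`.
#' @param phase `"stimulation"` or `"anticipation"`.
#' @param config a [decoding_config()].
#' @param N_perm group permutations per curve point.
#' @param seed master seed (per-point seeds derived).
#' @param schedule voxel counts (default [scale_schedule()] of the
#'   whole-brain size).
#' @param roi_points optional `region_decoding` result to overlay as
#'   `single_roi` points.
#' @return Data frame of class `scale_curve` with columns `scale_kind`,
#'   `label`, `n_features`, `accuracy`, `sem`, `p`; per-subject accuracies
#'   in `attr(, "subject_acc")`.
#' @export
scale_curve <- function(betas, phase = c("stimulation", "anticipation"),
                        config = decoding_config(), N_perm = 0, seed = NULL,
                        schedule = NULL, roi_points = NULL) {
  phase <- match.arg(phase)
  atlas <- betas[[1]]$atlas
  V <- length(feature_columns(feature_spec("whole_brain"), atlas,
                              ncol(betas[[1]]$patterns[[phase]])))
  schedule <- schedule %||% scale_schedule(V)
  specs <- lapply(schedule[schedule < V],
                  function(k) feature_spec("top_voxels", k = k))
  specs <- c(specs, list(feature_spec("whole_brain")))
  n_feat <- c(schedule[schedule < V], V)
  kinds <- c(rep("top_voxels", length(specs) - 1), "whole_brain")
  seeds <- derive_seeds(seed, length(specs))

  acc_mat <- matrix(NA_real_, length(betas), length(specs))
  out <- data.frame(scale_kind = kinds,
                    label = vapply(specs, format, character(1)),
                    n_features = n_feat, accuracy = NA_real_,
                    sem = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    g <- decode_group(betas, phase, specs[[i]], config,
                      N_perm = N_perm, seed = seeds[[i]])
    acc_mat[, i] <- g$subject_accuracies
    out$accuracy[i] <- g$mean_accuracy
    out$sem[i] <- g$sem
    out$p[i] <- g$p
  }
  colnames(acc_mat) <- out$label
  if (!is.null(roi_points)) {
    extra <- data.frame(scale_kind = "single_roi",
                        label = paste0("roi:", roi_points$region),
                        n_features = roi_points$n_voxels,
                        accuracy = roi_points$accuracy,
                        sem = roi_points$sem, p = roi_points$p,
                        stringsAsFactors = FALSE)
    sa <- attr(roi_points, "subject_acc")
    if (!is.null(sa)) {
      colnames(sa) <- extra$label
      acc_mat <- cbind(acc_mat, sa)
    }
    out <- rbind(out, extra)
  }
  attr(out, "subject_acc") <- acc_mat
  attr(out, "phase") <- phase
  rownames(out) <- NULL
  class(out) <- c("scale_curve", "data.frame")
  out
}

#' Compare two points of a scale curve
#'
#' Paired sign-flip permutation test on the per-subject accuracies of two
#' curve points (delegates to [paired_accuracy_comparison()]).
#'
#' @param curve a `scale_curve` (or any object with a per-subject accuracy
#'   matrix in `attr(, "subject_acc")`).
#' @param a,b point labels or column indices.
#' @param N,seed,exact passed to [paired_accuracy_comparison()].
#' @return p-value.
#' @export
compare_scales <- function(curve, a, b, N = 1000, seed = NULL, exact = NULL) {
  sa <- attr(curve, "subject_acc")
  if (is.null(sa)) stop("curve carries no per-subject accuracies")
  get_col <- function(id) {
    if (is.character(id)) {
      if (!id %in% colnames(sa)) stop("unknown curve point: ", id)
      sa[, id]
    } else sa[, as.integer(id)]
  }
  x <- get_col(a); y <- get_col(b)
  if (length(x) != length(y)) stop("points computed on different subjects")
  paired_accuracy_comparison(x, y, N = N, seed = seed, exact = exact)
}

#' Plot a scale curve
#'
#' Group mean accuracy +/- SEM against the number of features (log axis),
#' with the 50% chance level marked; single-ROI overlay points are drawn at
#' their mask sizes. Uses ggplot2 when available, base graphics otherwise.
#'
#' @param curve a `scale_curve`.
#' @return A ggplot object, or (base graphics) the curve invisibly.
#' @export
plot_scale_curve <- function(curve) {
  stopifnot(inherits(curve, "scale_curve"))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(curve, ggplot2::aes(x = n_features, y = accuracy,
                                        colour = scale_kind)) +
      ggplot2::geom_hline(yintercept = 0.5, colour = "grey60") +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = accuracy - sem,
                                            ymax = accuracy + sem)) +
      ggplot2::geom_line(data = curve[curve$scale_kind != "single_roi", ]) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "number of voxels", y = "decoding accuracy",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    main <- curve[curve$scale_kind != "single_roi", ]
    plot(main$n_features, main$accuracy, log = "x", type = "b",
         xlab = "number of voxels", ylab = "decoding accuracy",
         ylim = range(c(0.45, curve$accuracy + curve$sem,
                        curve$accuracy - curve$sem)))
    graphics::abline(h = 0.5, col = "grey60")
    roi <- curve[curve$scale_kind == "single_roi", ]
    if (nrow(roi)) graphics::points(roi$n_features, roi$accuracy,
                                    col = "darkgreen", pch = 17)
    invisible(curve)
  }
}
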