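# From beta series to classifier-ready feature matrices: per-voxel
# standardization (fit on training rows only, by default), per-trial l2
# scaling, ROI masking, discriminability ranking by two-sample t, and the
# tripling voxel-count schedule for the spatial-scale study.

#' Standardize features per voxel
#'
#' Centers and scales each column to mean 0, SD 1 using the population
#' (divide-by-n) convention, with parameters estimated on `fit_rows` only
#' (normally the training rows of the current cross-validation fold) and
#' applied to all rows. Zero-variance features on the fit rows carry no
#' information; their scale is set to 1 and they are flagged.
#'
#' @param x trials-by-features numeric matrix.
#' @param fit_rows row indices used to estimate mean and SD (>= 2; default
#'   all rows).
#' @return List with `values` (transformed matrix), `center`, `scale`
#'   (per-feature parameters) and `flagged` (zero-variance feature indices).
#' @export
standardize_voxels <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) < 2) stop("need >= 2 fit rows")
  xf <- x[fit_rows, , drop = FALSE]
  center <- colMeans(xf)
  sc <- sqrt(colMeans(xf^2) - center^2)   # population sd
  flagged <- which(sc <= 0 | !is.finite(sc))
  sc[flagged] <- 1
  list(values = sweep(sweep(x, 2, center), 2, sc, "/"),
       center = center, scale = sc, flagged = flagged)
}

#' Scale each trial pattern to unit Euclidean norm
#'
#' @param x trials-by-features matrix with no all-zero rows.
#' @return Matrix whose rows have l2 norm 1.
#' @export
l2_normalize_trials <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("cannot l2-normalize all-zero trial row(s): ",
         paste(zero, collapse = ", "))
  x / nrm
}

#' Restrict features to a union of atlas regions
#'
#' @param x a `beta_series` (use `phase` to pick the pattern matrix) or a
#'   trials-by-voxels matrix whose columns index the full grid.
#' @param atlas a `pain_atlas`.
#' @param regions character vector of region names (nonempty union).
#' @param phase which phase of a `beta_series` to extract.
#' @return Trials-by-voxels matrix restricted to the region union, with
#'   attributes `voxels` (grid linear indices) and `provenance`.
#' @export
apply_roi_mask <- function(x, atlas, regions,
                           phase = c("stimulation", "anticipation")) {
  phase <- match.arg(phase)
  if (inherits(x, "beta_series")) x <- x$patterns[[phase]]
  idx <- region_voxels(atlas, regions)
  out <- x[, idx, drop = FALSE]
  attr(out, "voxels") <- idx
  attr(out, "provenance") <-
    if (length(regions) == 1) paste0("roi:", regions)
    else paste0("roi_union:", paste(regions, collapse = "+"))
  out
}

#' Rank voxels by between-class t-score
#'
#' Two-sample pooled-variance t statistic per voxel, computed on training
#' rows only (call this inside each cross-validation fold; rankings must
#' never see test rows). Ranking is by |t| descending with stable
#' tie-breaking by voxel index; voxels with zero pooled variance but a
#' nonzero class difference get infinite |t|, sort first and are flagged.
#'
#' @param x training trials-by-voxels matrix.
#' @param labels training labels (`pain`/`no_pain` or -1/+1); both classes
#'   must be present.
#' @return Data frame ordered by rank with columns `voxel`, `t`, `flagged`.
#' @export
rank_voxels_tcontrast <- function(x, labels) {
  y <- to_pm1(labels)
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  x1 <- x[y > 0, , drop = FALSE]
  x0 <- x[y < 0, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  ss1 <- if (n1 > 1) colSums(sweep(x1, 2, m1)^2) else rep(0, ncol(x))
  ss0 <- if (n0 > 1) colSums(sweep(x0, 2, m0)^2) else rep(0, ncol(x))
  df <- n1 + n0 - 2
  sp2 <- if (df > 0) (ss1 + ss0) / df else rep(0, ncol(x))
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  t[se == 0 & (m1 - m0) == 0] <- 0
  t[se == 0 & (m1 - m0) != 0] <- sign((m1 - m0)[se == 0 & (m1 - m0) != 0]) * Inf
  ord <- order(abs(t), decreasing = TRUE)   # stable: ties keep voxel order
  data.frame(voxel = ord, t = t[ord], flagged = !is.finite(t[ord]))
}

#' Select the top-k ranked voxels
#'
#' @param x trials-by-voxels matrix the ranking refers to.
#' @param ranking output of [rank_voxels_tcontrast()].
#' @param k number of voxels (>= 1; capped at the number available).
#' @return Matrix restricted to the top `min(k, V)` voxels, with attributes
#'   `voxels` (column indices into `x`) and `provenance`.
#' @export
select_top_voxels <- function(x, ranking, k) {
  if (k < 1) stop("k must be >= 1")
  sel <- ranking$voxel[seq_len(min(k, nrow(ranking)))]
  out <- x[, sel, drop = FALSE]
  attr(out, "voxels") <- sel
  attr(out, "provenance") <- paste0("top_voxels:", length(sel))
  out
}

#' Voxel-count schedule for the spatial-scale study
#'
#' Powers of three starting at a single voxel, capped at the whole search
#' space: `1, 3, 9, ..., V`.
#'
#' @param n_voxels total number of voxels `V`.
#' @return Increasing integer vector ending at `V`.
#' @examples
#' scale_schedule(10)  # 1 3 9 10
#' @export
scale_schedule <- function(n_voxels) {
  stopifnot(n_voxels >= 1)
  ks <- 3^(0:floor(log(n_voxels) / log(3) + 1e-9))
  unique(c(ks[ks <= n_voxels], n_voxels))
}

#' Describe a decoding feature space
#'
#' @param type `whole_brain` (all atlas voxels), `pain_matrix` (all
#'   non-control regions), `roi` / `roi_union` (named regions), or
#'   `top_voxels` (the `k` most discriminative voxels, re-ranked inside
#'   every training fold).
#' @param regions region names, for the ROI types.
#' @param k voxel count, for `top_voxels`.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(type = c("whole_brain", "pain_matrix", "roi",
                                  "roi_union", "top_voxels"),
                         regions = NULL, k = NULL) {
  type <- match.arg(type)
  if (type %in% c("roi", "roi_union") && is.null(regions))
    stop("regions must be given for ROI feature specs")
  if (type == "roi" && length(regions) != 1)
    stop("type 'roi' takes exactly one region; use 'roi_union' for several")
  if (type == "top_voxels" && (is.null(k) || k < 1))
    stop("k >= 1 must be given for top_voxels")
  structure(list(type = type, regions = regions, k = k),
            class = "feature_spec")
}

#' @export
format.feature_spec <- function(x, ...) {
  switch(x$type,
         whole_brain = "whole_brain",
         pain_matrix = "pain_matrix",
         roi = paste0("roi:", x$regions),
         roi_union = paste0("roi_union:", paste(x$regions, collapse = "+")),
         top_voxels = paste0("top_voxels:", x$k))
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec>", format(x), "\n")
  invisible(x)
}

# resolve a feature spec to base voxel columns of a beta-series pattern
# matrix; top_voxels resolves to the whole-brain candidate set (selection
# happens per training fold)
feature_columns <- function(spec, atlas, n_cols) {
  if (is.null(atlas)) {
    if (spec$type %in% c("roi", "roi_union", "pain_matrix"))
      stop("beta series carries no atlas; ROI feature specs unavailable")
    return(seq_len(n_cols))
  }
  switch(spec$type,
         whole_brain = region_voxels(atlas, NULL),
         top_voxels = region_voxels(atlas, NULL),
         pain_matrix = region_voxels(
           atlas, setdiff(atlas$region_names, atlas$control_regions)),
         roi = ,
         roi_union = region_voxels(atlas, spec$regions))
}
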