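# File formats: NIfTI-1 for volumes, atlases, beta images and t-maps
# (via RNifti); tab-separated tables for events, trial metadata and result
# tables; JSON sidecars and run manifests.

#' Write a volume to NIfTI-1
#'
#' @param x 3D or 4D numeric array (NaN/NA values are preserved, e.g.
#'   flagged voxels of a t-map).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size_mm isotropic voxel size for the header.
#' @param TR repetition time stored in the 4th pixdim (4D only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = 3, TR = NULL) {
  nd <- length(dim(x))
  if (!nd %in% c(3, 4)) stop("x must be a 3D or 4D array")
  pixdim <- c(rep(voxel_size_mm, 3), if (nd == 4) TR %||% 1)
  img <- RNifti::asNifti(x, internal = FALSE)
  img <- RNifti::`pixdim<-`(img, pixdim)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path NIfTI file.
#' @return Numeric array with attributes `voxel_size_mm` and (4D) `TR`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- pd[1]
  if (length(dim(out)) == 4) attr(out, "TR") <- pd[4]
  out
}

#' Write a synthetic dataset to a directory
#'
#' Volumes as 4D NIfTI-1, events as TSV, the atlas as an integer NIfTI-1
#' with a JSON name-mapping sidecar, and a dataset sidecar holding TR,
#' session structure and the ground-truth summary.
#'
#' @param subject a `pain_subject`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(subject, dir) {
  stopifnot(inherits(subject, "pain_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(subject$volumes, file.path(dir, "bold.nii.gz"),
               subject$atlas$voxel_size_mm, subject$TR)
  ev <- subject$events
  write.table(as.data.frame(ev), file.path(dir, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_atlas(subject$atlas, dir)
  truth <- subject$truth
  side <- list(subject_id = subject$subject_id, TR = subject$TR,
               seed = subject$seed,
               session_n_volumes = subject$session_n_volumes,
               session_duration = attr(ev, "session_duration"),
               truth = list(informative_regions = truth$informative_regions,
                            effect_size = truth$effect_size,
                            effect_size_mean = truth$effect_size_mean,
                            effect_size_sd = truth$effect_size_sd,
                            phase = truth$phase, noise_sd = truth$noise_sd,
                            ar1_rho = truth$ar1_rho,
                            drift_amplitude = truth$drift_amplitude,
                            base_amplitude = truth$base_amplitude))
  jsonlite::write_json(side, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_atlas <- function(atlas, dir) {
  write_volume(array(as.numeric(atlas$labels), dim = atlas$grid_shape),
               file.path(dir, "atlas.nii.gz"), atlas$voxel_size_mm)
  jsonlite::write_json(
    list(region_names = atlas$region_names,
         control_regions = atlas$control_regions,
         voxel_size_mm = atlas$voxel_size_mm),
    file.path(dir, "atlas.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_atlas <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  vol <- read_volume(file.path(dir, "atlas.nii.gz"))
  structure(list(labels = array(as.integer(round(vol)), dim = dim(vol)),
                 region_names = side$region_names,
                 control_regions = side$control_regions %||% character(0),
                 grid_shape = dim(vol),
                 voxel_size_mm = side$voxel_size_mm %||% 3),
            class = "pain_atlas")
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return A `pain_subject` (ground truth restored from the sidecar; the
#'   informative-voxel mask is rebuilt from the atlas).
#' @export
read_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  atlas <- read_atlas(dir)
  ev <- read.table(file.path(dir, "events.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  attr(ev, "session_duration") <- side$session_duration
  class(ev) <- c("pain_events", "data.frame")
  tr <- side$truth
  spec <- signal_spec(atlas, tr$informative_regions %||% character(0),
                      tr$effect_size_mean, tr$effect_size_sd, tr$phase,
                      tr$noise_sd, tr$ar1_rho, tr$drift_amplitude,
                      tr$base_amplitude)
  spec$effect_size <- tr$effect_size
  structure(list(volumes = read_volume(file.path(dir, "bold.nii.gz")),
                 TR = side$TR, events = ev, atlas = atlas, truth = spec,
                 subject_id = side$subject_id, seed = side$seed,
                 session_n_volumes = side$session_n_volumes),
            class = "pain_subject")
}

#' Write a beta series to a directory
#'
#' One 4D NIfTI per phase (trials along the 4th axis), trial metadata as
#' TSV, and a JSON sidecar with grid and provenance.
#'
#' @param beta a `beta_series` with a `grid_shape`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_beta_series <- function(beta, dir) {
  stopifnot(inherits(beta, "beta_series"))
  if (is.null(beta$grid_shape)) stop("beta series carries no grid_shape")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in names(beta$patterns)) {
    arr <- array(t(beta$patterns[[ph]]),
                 dim = c(beta$grid_shape, nrow(beta$meta)))
    write_volume(arr, file.path(dir, paste0("beta_", ph, ".nii.gz")))
  }
  write.table(beta$meta, file.path(dir, "trials.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = beta$subject_id,
                            grid_shape = beta$grid_shape, rho = beta$rho),
                       file.path(dir, "beta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(beta$atlas)) write_atlas(beta$atlas, dir)
  invisible(dir)
}

#' Read a beta series written by [write_beta_series()]
#'
#' @param dir directory.
#' @return A `beta_series`.
#' @export
read_beta_series <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "beta.json"),
                              simplifyVector = TRUE)
  meta <- read.table(file.path(dir, "trials.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  pats <- lapply(c(anticipation = "anticipation", stimulation = "stimulation"),
                 function(ph) {
    arr <- read_volume(file.path(dir, paste0("beta_", ph, ".nii.gz")))
    t(matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4]))
  })
  atlas <- if (file.exists(file.path(dir, "atlas.json"))) read_atlas(dir)
  beta_series(pats$anticipation, pats$stimulation, meta,
              grid_shape = side$grid_shape, atlas = atlas,
              subject_id = side$subject_id, rho = side$rho %||% NA_real_)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run: configuration snapshot,
#' seeds, input file hashes, package and R versions, timestamp.
#'
#' @param config configuration list.
#' @param seed master seed.
#' @param inputs character vector of input file paths to hash.
#' @return Manifest list.
#' @export
run_manifest <- function(config, seed = NULL, inputs = character(0)) {
  list(package = "painscale",
       package_version = as.character(packageVersion("painscale")),
       r_version = as.character(getRversion()),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)),
       config = config)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
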