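#' Read / write 4D signal volumes as NIfTI with a JSON sidecar
#'
#' Volumes are stored as NIfTI-1 via the RNifti package; the acquisition
#' constants (TE, TR, S0, kappa and an optional partial-volume correction
#' factor) travel in a JSON sidecar next to the image.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`); the sidecar is
#'   `<path without extension>.json`.
#' @param volume 4D numeric array.
#' @param consts an [acquisition_constants] object.
#' @param pvc_factor optional partial-volume correction factor stored in the
#'   sidecar.
#' @return `write_volume` invisibly returns `path`; `read_volume` returns a
#'   list with `volume` (4D array) and `consts`.
#' @export
write_volume <- function(path, volume, consts, pvc_factor = NULL) {
  stopifnot(length(dim(volume)) == 4L,
            inherits(consts, "acquisition_constants"))
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  side <- list(te = consts$te, tr = consts$tr, s0 = consts$s0,
               kappa = consts$kappa)
  if (!is.null(pvc_factor)) side$pvc_factor <- pvc_factor
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("missing JSON sidecar '%s'", sp), call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  need <- c("te", "tr", "s0", "kappa")
  missing <- setdiff(need, names(side))
  if (length(missing))
    stop(sprintf("sidecar is missing required keys: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  consts <- acquisition_constants(te = side$te, tr = side$tr, s0 = side$s0,
                                  kappa = side$kappa)
  list(volume = vol, consts = consts,
       pvc_factor = side$pvc_factor %||% NULL)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write perfusion maps as 3D NIfTI images
#'
#' One image per parameter map, named `<prefix>_<map>.nii.gz`.
#'
#' @param maps a `perfusion_maps` object from [fit_volume].
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "perfusion_maps"))
  written <- character(0)
  for (nm in c("cbf", "mtt", "cbv", "delay", "vtf_s", "vtf_p")) {
    if (all(!is.finite(maps[[nm]]))) next
    f <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), f)
    written <- c(written, f)
  }
  invisible(written)
}

#' Write a simulated dataset to plain-text fixtures
#'
#' Emits the truth table as CSV, every noisy tissue/arterial curve as
#' two-column CSV, and the configuration as JSON, for provenance and for
#' consumption by external tools.
#'
#' @param ds a `sim_dataset` from [simulate_dataset].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_sim_fixtures <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  for (v in seq_along(ds$voxels)) {
    write_curve_csv(ds$voxels[[v]]$ctc,
                    file.path(dir, sprintf("ctc_%04d.csv", v)))
    write_curve_csv(ds$voxels[[v]]$aif,
                    file.path(dir, sprintf("aif_%04d.csv", v)))
  }
  cfg <- ds$config
  cfg$condition_id <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
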