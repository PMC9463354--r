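#' Voxelwise perfusion map fitting of a 4D signal volume
#'
#' Applies [bzd] (or [osvd]) to every in-mask voxel of a 4D signal array:
#' each voxel's signal is converted to concentration with the supplied
#' acquisition constants, deconvolved against the shared AIF, and the
#' per-voxel estimates are written into parameter maps. CBV is computed from
#' the curve-area ratio independently of the fit. Voxel failures are
#' recorded as `NaN` and counted.
#'
#' @param signal_4d 4D numeric array (x, y, z, time) of MRI signal.
#' @param aif arterial input function as a concentration [uniform_curve]
#'   on the acquisition grid.
#' @param consts an [acquisition_constants] object (TE, TR, S0, kappa).
#' @param variant [bzd] variant name, or `"osvd"` for the reference method.
#' @param mask logical/numeric 3D array selecting voxels; default all.
#' @param oi oscillation-index threshold when `variant = "osvd"`.
#' @param control [bzd_control] for the fits.
#' @param verbose print a progress line per slice batch.
#' @return A list of class `perfusion_maps`: 3D arrays `cbf`
#'   (ml/100 g/min), `mtt` (s), `cbv` (%), `delay` (s), `vtf_s`, `vtf_p`,
#'   `converged`, plus `n_failed` and the call.
#' @export
fit_volume <- function(signal_4d, aif, consts, variant = "plain",
                       mask = NULL, oi = 0.095, control = bzd_control(),
                       verbose = FALSE) {
  stopifnot(length(dim(signal_4d)) == 4L, inherits(aif, "uniform_curve"),
            inherits(consts, "acquisition_constants"))
  dims <- dim(signal_4d)
  nt <- dims[4]
  if (nt != length(aif$values))
    stop("time dimension does not match the AIF length", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!all(dim(mask) == dims[1:3]))
    stop("mask dimensions do not match the volume", call. = FALSE)
  mk <- function() array(NaN, dims[1:3])
  maps <- list(cbf = mk(), mtt = mk(), cbv = mk(), delay = mk(),
               vtf_s = mk(), vtf_p = mk(), converged = mk())
  idx <- which(mask != 0, arr.ind = TRUE)
  n_failed <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sig <- uniform_curve(signal_4d[i, j, k, ], dt = consts$tr, t0 = 0)
    res <- tryCatch({
      ctc <- signal_to_concentration(sig, consts)
      if (identical(variant, "osvd")) {
        f <- osvd(ctc, aif, osvd_settings(oi_threshold = oi),
                  kappa = consts$kappa)
        list(cbf = f$cbf, mtt = f$mtt, cbv = f$cbv, delay = f$delay,
             s = NA_real_, p = NA_real_, conv = 1)
      } else {
        f <- bzd(ctc, aif, variant = variant, kappa = consts$kappa,
                 control = control)
        list(cbf = f$cbf, mtt = f$mtt, cbv = f$cbv, delay = f$delay,
             s = if (is.null(f$vtf)) NA_real_ else f$vtf[["s"]],
             p = if (is.null(f$vtf)) NA_real_ else f$vtf[["p"]],
             conv = as.numeric(f$converged))
      }
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    maps$cbf[i, j, k] <- res$cbf * CBF_TO_CLINICAL
    maps$mtt[i, j, k] <- res$mtt
    maps$cbv[i, j, k] <- 100 * res$cbv
    maps$delay[i, j, k] <- res$delay
    maps$vtf_s[i, j, k] <- res$s
    maps$vtf_p[i, j, k] <- res$p
    maps$converged[i, j, k] <- res$conv
    if (verbose && r %% 100 == 0)
      message(sprintf("fit_volume: %d / %d voxels", r, nrow(idx)))
  }
  structure(c(maps, list(n_failed = n_failed, variant = variant,
                         call = match.call())),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("perfusion maps (variant: %s), %d failed voxel(s)\n",
              x$variant, x$n_failed))
  for (nm in c("cbf", "mtt", "cbv")) {
    v <- x[[nm]][is.finite(x[[nm]])]
    if (length(v))
      cat(sprintf("  %-4s mean %.2f sd %.2f (n = %d)\n", nm, mean(v),
                  stats::sd(v), length(v)))
  }
  invisible(x)
}

#' Large-vessel exclusion and whole-volume summary
#'
#' Single-pass rule used for whole-brain map summaries: voxels whose value
#' exceeds `factor` times the mean over all finite voxels are assumed to
#' originate from large vessels and are excluded from the reported
#' mean and standard deviation.
#'
#' @param map_values numeric array or vector of map values.
#' @param factor exclusion threshold multiplier (default 2.5).
#' @return A list with `mask` (logical, `TRUE` = kept; same shape as the
#'   input), `threshold`, `n_excluded`, `mean` and `sd` of the kept voxels.
#' @export
exclude_large_vessels <- function(map_values, factor = 2.5) {
  finite <- is.finite(map_values)
  if (!any(finite)) stop("map has no finite voxels", call. = FALSE)
  threshold <- factor * mean(map_values[finite])
  keep <- finite & (map_values <= threshold)
  v <- map_values[keep]
  list(mask = keep & array(TRUE, dim = dim(map_values) %||% length(map_values)),
       threshold = threshold,
       n_excluded = sum(finite) - sum(keep),
       mean = mean(v), sd = stats::sd(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
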