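#' Acquisition constants
#'
#' Echo time, repetition time, baseline signal and the hematocrit/density
#' constant \eqn{\kappa} used in the tracer-kinetic relations. In simulations
#' \eqn{\kappa = 1}; for in-vivo data the conventional value is
#' 0.705 cm\eqn{^3}/g.
#'
#' @param te echo time (s).
#' @param tr repetition time (s).
#' @param s0 baseline (pre-contrast) signal, arbitrary units.
#' @param kappa hematocrit/density correction constant.
#' @return A list of class `acquisition_constants`.
#' @export
acquisition_constants <- function(te, tr, s0, kappa = 1) {
  for (nm in c("te", "tr", "s0", "kappa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a single positive number", nm), call. = FALSE)
  }
  structure(list(te = te, tr = tr, s0 = s0, kappa = kappa),
            class = "acquisition_constants")
}

#' Convert MRI signal to contrast-agent concentration
#'
#' Uses the standard linear relation between concentration and the change in
#' transverse relaxation rate:
#' \eqn{C(t) = -\ln(S(t)/S_0)/TE}, with the proportionality constant taken as 1
#' (the absolute concentration scale is absorbed by \eqn{\kappa} and the
#' signal-model constant \eqn{\xi}).
#'
#' @param signal a [uniform_curve] of MRI signal values (all positive).
#' @param consts an [acquisition_constants] object (uses `te` and `s0`).
#' @return A [uniform_curve] of concentrations on the same grid.
#' @export
signal_to_concentration <- function(signal, consts) {
  stopifnot(inherits(signal, "uniform_curve"),
            inherits(consts, "acquisition_constants"))
  bad <- which(signal$values <= 0)
  if (length(bad))
    stop(sprintf("non-positive signal at sample index %d", bad[1]),
         call. = FALSE)
  uniform_curve(-log(signal$values / consts$s0) / consts$te,
                dt = signal$dt, t0 = signal$t0)
}

#' Convert concentration to MRI signal
#'
#' Exponential signal model \eqn{S(t) = S_0 e^{-\xi C(t) TE}}; baseline
#' concentration zero maps to \eqn{S_0}.
#'
#' @param conc a [uniform_curve] of concentrations.
#' @param s0 baseline signal.
#' @param te echo time (s).
#' @param xi concentration-to-relaxivity scaling constant (see
#'   [calibrate_xi]).
#' @return A [uniform_curve] of signal values.
#' @export
concentration_to_signal <- function(conc, s0, te, xi = 1) {
  stopifnot(inherits(conc, "uniform_curve"))
  if (!is.numeric(s0) || s0 <= 0) stop("s0 must be positive", call. = FALSE)
  uniform_curve(s0 * exp(-xi * conc$values * te), dt = conc$dt, t0 = conc$t0)
}

#' Causal discrete convolution of two uniform curves
#'
#' Rectangle-rule discretization of \eqn{\int_0^t f(\tau) g(t-\tau) d\tau}:
#' `out[k] = dt * sum_j f[j] g[k-j]`, truncated to the length of `f`. The
#' output start time is the sum of the input start times.
#'
#' @param f,g [uniform_curve]s sharing the same `dt`.
#' @return A [uniform_curve] of the same length as `f`.
#' @export
convolve_uniform <- function(f, g) {
  stopifnot(inherits(f, "uniform_curve"), inherits(g, "uniform_curve"))
  check_same_dt(f, g)
  uniform_curve(cpp_conv(f$values, g$values, f$dt),
                dt = f$dt, t0 = f$t0 + g$t0)
}

#' Shift a curve in time
#'
#' Returns the curve evaluated at \eqn{t - \delta} (positive `delta` = later
#' arrival). Sub-sample shifts are supported through cubic-spline
#' interpolation; the pre-bolus region is filled with zeros (curves are
#' baseline-subtracted concentrations).
#'
#' @param curve a [uniform_curve].
#' @param delta shift in seconds.
#' @return A shifted [uniform_curve] on the same grid.
#' @export
shift_curve <- function(curve, delta) {
  stopifnot(inherits(curve, "uniform_curve"))
  if (!is.finite(delta)) stop("delta must be finite", call. = FALSE)
  n <- length(curve$values)
  if (abs(delta) >= n * curve$dt)
    warning("shift exceeds record length; result is all zero")
  uniform_curve(cpp_shift_curve(curve$values, curve$dt, delta),
                dt = curve$dt, t0 = curve$t0)
}

#' Gamma vascular transport function (dispersion kernel)
#'
#' Gamma-family kernel
#' \eqn{VTF(t) = s^{1+sp} t^{sp} e^{-st} / \Gamma(1+sp)} with sharpness `s`
#' (1/s) and time-to-peak `p` (s); the continuous kernel has its mode at
#' \eqn{t = p}. The sampled kernel is renormalized to unit discrete area
#' (`sum * dt == 1`) so that dispersion never changes the blood volume.
#'
#' @param s sharpness (1/s), positive.
#' @param p time-to-peak (s), non-negative.
#' @param grid a [uniform_curve] supplying the output grid (dt and length).
#' @return A [uniform_curve] containing the kernel.
#' @export
gamma_vtf <- function(s, p, grid) {
  stopifnot(inherits(grid, "uniform_curve"))
  if (!is.numeric(s) || s <= 0) stop("s must be positive", call. = FALSE)
  if (!is.numeric(p) || p < 0) stop("p must be non-negative", call. = FALSE)
  uniform_curve(cpp_gamma_vtf(s, p, grid$dt, length(grid$values)),
                dt = grid$dt, t0 = 0)
}

#' Tracer-kinetic forward model
#'
#' Predicted tissue concentration curve
#' \eqn{C(t) = \kappa\, CBF \, (C_a(t-\delta) \otimes VTF(t) \otimes R(t))}.
#' With `delta = NULL` and `vtf = NULL` this reduces exactly to the plain
#' convolution model \eqn{C = \kappa\,CBF\,(C_a \otimes R)}.
#'
#' @param aif arterial input function, a [uniform_curve].
#' @param residue residue function sampled on the AIF grid.
#' @param cbf blood flow in internal units (ml/g/s), non-negative.
#' @param kappa hematocrit/density constant (1 in simulations).
#' @param delta arterial delay in seconds, or `NULL` for none.
#' @param vtf dispersion kernel: `NULL` for none, a [uniform_curve], or a
#'   numeric `c(s, p)` pair passed to [gamma_vtf].
#' @return The predicted concentration [uniform_curve].
#' @export
forward_model <- function(aif, residue, cbf, kappa = 1, delta = NULL,
                          vtf = NULL) {
  stopifnot(inherits(aif, "uniform_curve"), inherits(residue, "uniform_curve"))
  check_same_dt(aif, residue)
  if (cbf < 0) stop("cbf must be non-negative", call. = FALSE)
  a <- aif
  if (!is.null(delta)) a <- shift_curve(a, delta)
  if (!is.null(vtf)) {
    if (is.numeric(vtf) && length(vtf) == 2L) vtf <- gamma_vtf(vtf[1], vtf[2], a)
    a <- convolve_uniform(a, vtf)
  }
  out <- convolve_uniform(a, residue)
  uniform_curve(kappa * cbf * out$values, dt = out$dt, t0 = out$t0)
}

#' Mean transit time from a residue function
#'
#' Trapezoidal integral of the sampled residue function,
#' \eqn{MTT = \int_0^\infty R(t) dt}, over the sampled support.
#'
#' @param residue a [uniform_curve] (values non-negative).
#' @return MTT in seconds.
#' @export
mtt_from_residue <- function(residue) {
  stopifnot(inherits(residue, "uniform_curve"))
  trapz(residue$values, residue$dt)
}

#' Cerebral blood volume from concentration curves
#'
#' \eqn{CBV = \kappa \int C(t) dt / \int C_a(t) dt}, trapezoidal rule.
#'
#' @param ctc tissue concentration curve.
#' @param aif arterial input function.
#' @param kappa hematocrit/density constant.
#' @return CBV in ml/g (a fraction when \eqn{\kappa = 1}).
#' @export
cbv_from_curves <- function(ctc, aif, kappa = 1) {
  stopifnot(inherits(ctc, "uniform_curve"), inherits(aif, "uniform_curve"))
  aif_area <- trapz(aif$values, aif$dt)
  if (aif_area <= 0) stop("AIF area must be positive", call. = FALSE)
  kappa * trapz(ctc$values, ctc$dt) / aif_area
}
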