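#' Gaussian prior specification for Bezier deconvolution
#'
#' Independent Gaussian priors per fitted parameter. Defaults follow the
#' standard specification for the method: control-point means
#' `[8, 0.5, 2, 0.2, 15]` with standard deviations `[8, 1, 4, 1, 100]`;
#' a non-informative CBF prior (mean 0.01 ml/g/s, sd 1e6); delay sd 5 s;
#' dispersion-kernel parameters \eqn{(s, p)} with means \eqn{(\ln 2, \ln 2)}
#' and sds (2, 2).
#'
#' @param cp_mean,cp_sd control-point prior means and sds, in the order
#'   `p1x, p1y, p2x, p2y, p3x`.
#' @param cbf_mean,cbf_sd CBF prior (internal units, ml/g/s).
#' @param delay_mean,delay_sd arterial delay prior (s). The default delay
#'   mean is data-driven; see [default_priors].
#' @param vtf_mean,vtf_sd priors for the gamma dispersion kernel `(s, p)`.
#' @return A list of class `bzd_priors`.
#' @export
bzd_priors <- function(cp_mean = c(8, 0.5, 2, 0.2, 15),
                       cp_sd = c(8, 1, 4, 1, 100),
                       cbf_mean = 0.01, cbf_sd = 1e6,
                       delay_mean = 0, delay_sd = 5,
                       vtf_mean = c(log(2), log(2)),
                       vtf_sd = c(2, 2)) {
  stopifnot(length(cp_mean) == 5L, length(cp_sd) == 5L,
            length(vtf_mean) == 2L, length(vtf_sd) == 2L)
  if (any(c(cp_sd, cbf_sd, delay_sd, vtf_sd) <= 0))
    stop("all prior standard deviations must be positive", call. = FALSE)
  structure(list(cp_mean = as.numeric(cp_mean), cp_sd = as.numeric(cp_sd),
                 cbf_mean = cbf_mean, cbf_sd = cbf_sd,
                 delay_mean = delay_mean, delay_sd = delay_sd,
                 vtf_mean = as.numeric(vtf_mean), vtf_sd = as.numeric(vtf_sd)),
            class = "bzd_priors")
}

#' Default priors with a data-driven delay prior mean
#'
#' Returns the standard priors of [bzd_priors] with the delay prior mean set
#' to the (non-negative) difference in time-to-peak between the measured
#' tissue curve and the AIF, with proportionality constant 1.
#'
#' @param aif arterial input function, a [uniform_curve].
#' @param ctc tissue concentration curve, a [uniform_curve].
#' @param variant a [bzd_variant] (only used to decide whether the delay
#'   prior is needed); defaults to the plain model.
#' @return A `bzd_priors` object.
#' @export
default_priors <- function(aif, ctc, variant = bzd_variant("plain")) {
  pr <- bzd_priors()
  if (variant$delay_on) {
    if (max(aif$values) <= min(aif$values) ||
        max(ctc$values) <= min(ctc$values)) {
      warning("flat curve(s): delay prior mean set to 0")
      pr$delay_mean <- 0
    } else {
      tp_aif <- curve_time(aif)[which.max(aif$values)]
      tp_ctc <- curve_time(ctc)[which.max(ctc$values)]
      pr$delay_mean <- max(0, tp_ctc - tp_aif)
    }
  }
  pr
}

#' Model variant for Bezier deconvolution
#'
#' Selects which distortion parameters are fitted alongside the residue
#' function and CBF: arterial delay \eqn{\delta} and/or the gamma dispersion
#' kernel \eqn{(s, p)}. The parameter vector has length
#' `6 + delay_on + 2 * dispersion_on`.
#'
#' @param name one of `"plain"`, `"delay"`, `"disp"`, `"delay-disp"`.
#' @return A list of class `bzd_variant` with flags `delay_on`,
#'   `dispersion_on` and the parameter names.
#' @export
bzd_variant <- function(name = c("plain", "delay", "disp", "delay-disp")) {
  name <- match.arg(name)
  delay_on <- name %in% c("delay", "delay-disp")
  disp_on <- name %in% c("disp", "delay-disp")
  pn <- c("p1x", "p1y", "p2x", "p2y", "p3x", "cbf")
  if (delay_on) pn <- c(pn, "delay")
  if (disp_on) pn <- c(pn, "vtf_s", "vtf_p")
  structure(list(name = name, delay_on = delay_on, dispersion_on = disp_on,
                 par_names = pn),
            class = "bzd_variant")
}

# internal: prior mean / sd vectors ordered like the parameter vector
prior_vectors <- function(priors, variant) {
  m <- c(priors$cp_mean, priors$cbf_mean)
  s <- c(priors$cp_sd, priors$cbf_sd)
  if (variant$delay_on) {
    m <- c(m, priors$delay_mean); s <- c(s, priors$delay_sd)
  }
  if (variant$dispersion_on) {
    m <- c(m, priors$vtf_mean); s <- c(s, priors$vtf_sd)
  }
  list(mean = m, sd = s)
}
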