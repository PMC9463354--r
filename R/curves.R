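#' Uniformly sampled time curve
#'
#' The basic carrier for all time series handled by the package: MRI signal
#' \eqn{S(t)}, tissue concentration \eqn{C(t)}, arterial input function
#' \eqn{C_a(t)}, residue functions \eqn{R(t)} and dispersion kernels. Sample
#' \eqn{k} (1-based in R) sits at time \eqn{t_0 + (k-1)\,dt}.
#'
#' @param values numeric vector of samples (length at least 2, all finite).
#' @param dt sample spacing in seconds (the repetition time TR for measured
#'   data); must be positive.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `uniform_curve`: a list with elements `t0`,
#'   `dt` and `values`.
#' @examples
#' uc <- uniform_curve(exp(-(0:99) * 0.5 / 12), dt = 0.5)
#' curve_time(uc)[1:5]
#' @export
uniform_curve <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a uniform_curve needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("curve values must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  structure(list(t0 = as.numeric(t0), dt = dt, values = values),
            class = "uniform_curve")
}

#' Sampling times of a uniform curve
#' @param x a [uniform_curve].
#' @return Numeric vector of sample times in seconds.
#' @export
curve_time <- function(x) {
  stopifnot(inherits(x, "uniform_curve"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.uniform_curve <- function(x, ...) {
  cat(sprintf("uniform_curve: %d samples, dt = %g s, t0 = %g s, range [%g, %g]\n",
              length(x$values), x$dt, x$t0, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.uniform_curve <- function(x, ...) {
  data.frame(time_s = curve_time(x), value = x$values)
}

#' @export
length.uniform_curve <- function(x) length(x$values)

# internal: check two curves share a grid spacing
check_same_dt <- function(f, g) {
  if (abs(f$dt - g$dt) > 1e-9 * max(f$dt, g$dt))
    stop("curves must share the same sample spacing dt", call. = FALSE)
  invisible(TRUE)
}

#' Read / write a curve as two-column CSV
#'
#' Curves are serialized as CSV with columns `time_s` and `value`. On read,
#' the time column must be uniformly spaced.
#'
#' @param path file path.
#' @return `read_curve_csv` returns a [uniform_curve]; `write_curve_csv`
#'   invisibly returns `path`.
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("curve CSV must have columns 'time_s' and 'value'", call. = FALSE)
  tt <- d$time_s
  if (length(tt) < 2L) stop("curve CSV needs at least 2 rows", call. = FALSE)
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("curve CSV time column is not uniformly spaced", call. = FALSE)
  uniform_curve(d$value, dt = mean(dts), t0 = tt[1])
}

#' @rdname read_curve_csv
#' @param curve a [uniform_curve] to write.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "uniform_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

# internal: trapezoidal integral of sampled values with spacing dt
trapz <- function(values, dt) {
  n <- length(values)
  if (n < 2L) return(0)
  dt * (sum(values) - 0.5 * (values[1] + values[n]))
}
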