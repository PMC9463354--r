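#' Bernstein basis polynomial
#'
#' \eqn{B_i^n(\tau) = \binom{n}{i} \tau^i (1-\tau)^{n-i}} for
#' \eqn{\tau \in [0,1]}. The Bernstein basis forms a partition of unity, which
#' makes every point on a Bezier curve a convex combination of its control
#' points.
#'
#' @param n degree (non-negative integer).
#' @param i index, `0 <= i <= n`.
#' @param tau parameter value(s) in `[0, 1]`; vectorized.
#' @return Numeric weights, same length as `tau`.
#' @export
bernstein <- function(n, i, tau) {
  if (i < 0 || i > n) stop("index i must satisfy 0 <= i <= n", call. = FALSE)
  if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]", call. = FALSE)
  choose(n, i) * tau^i * (1 - tau)^(n - i)
}

#' Cubic Bezier control points for a residue function
#'
#' Five free parameters; the anchors \eqn{P_0 = (0, 1)} (so that
#' \eqn{R(0) = 1}) and \eqn{P_{3,y} = 0} (bounded-input bounded-output
#' stability) are fixed. The feasible region is
#' \eqn{0 \le P_{i,y} \le 1}, \eqn{0 \le P_{i,x} \le P_{3,x}},
#' \eqn{P_{3,x} > 0}; during fitting, violations are penalized rather than
#' clamped.
#'
#' @param p1x,p1y,p2x,p2y,p3x coordinates of the free control points; time
#'   coordinates in seconds, amplitudes dimensionless.
#' @return An object of class `control_points` (named numeric vector in the
#'   order `p1x, p1y, p2x, p2y, p3x`).
#' @export
control_points <- function(p1x, p1y, p2x, p2y, p3x) {
  v <- c(p1x = p1x, p1y = p1y, p2x = p2x, p2y = p2y, p3x = p3x)
  if (!all(is.finite(v))) stop("control points must be finite", call. = FALSE)
  structure(v, class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  cat("cubic Bezier control points (P0 = (0,1), P3y = 0 fixed):\n")
  print(unclass(x))
  invisible(x)
}

# internal: accept a control_points object or a plain 5-vector
as_ctrl <- function(points) {
  if (inherits(points, "control_points")) return(unclass(points))
  if (is.numeric(points) && length(points) == 5L) return(as.numeric(points))
  stop("expected control_points or a numeric 5-vector", call. = FALSE)
}

#' Evaluate a cubic Bezier curve
#'
#' \eqn{B_3(\tau) = (1-\tau)^3 P_0 + 3(1-\tau)^2\tau P_1 +
#' 3(1-\tau)\tau^2 P_2 + \tau^3 P_3} with the fixed anchors of
#' [control_points]. The curve starts at \eqn{(0, 1)}, ends at
#' \eqn{(P_{3,x}, 0)}, and lies inside the convex hull of the four control
#' points.
#'
#' @param points a [control_points] object (or numeric 5-vector).
#' @param taus ascending parameter values in `[0, 1]`.
#' @return A data frame with columns `x` (time, s) and `y` (amplitude).
#' @export
bezier_eval <- function(points, taus) {
  ctrl <- as_ctrl(points)
  if (any(taus < 0 | taus > 1)) stop("tau must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(taus)) stop("taus must be sorted ascending", call. = FALSE)
  b0 <- (1 - taus)^3
  b1 <- 3 * (1 - taus)^2 * taus
  b2 <- 3 * (1 - taus) * taus^2
  b3 <- taus^3
  data.frame(x = b1 * ctrl[1] + b2 * ctrl[3] + b3 * ctrl[5],
             y = b0 * 1 + b1 * ctrl[2] + b2 * ctrl[4])
}

#' Sample a Bezier residue function on a time grid
#'
#' The parametric cubic Bezier curve is evaluated densely (consecutive time
#' samples at most 10 ms apart), repaired to a strictly increasing time
#' coordinate if needed, and resampled onto the output grid by cubic-spline
#' interpolation. By construction \eqn{R(0) = 1} exactly and
#' \eqn{R(t > P_{3,x}) = 0}.
#'
#' @param points a [control_points] object (or numeric 5-vector).
#' @param grid a [uniform_curve] supplying the output grid.
#' @return A [uniform_curve] with the sampled residue function.
#' @export
residue_from_controls <- function(points, grid) {
  ctrl <- as_ctrl(points)
  stopifnot(inherits(grid, "uniform_curve"))
  if (!(ctrl[5] > 0))
    stop("infeasible control points: p3x must be positive", call. = FALSE)
  out <- cpp_bezier_residue(ctrl, grid$dt, length(grid$values))
  uniform_curve(out$values, dt = grid$dt, t0 = 0)
}

#' Constraint penalty for Bezier residue fitting
#'
#' Smooth quadratic exterior penalty used inside the posterior: zero for
#' feasible control points whose sampled residue is monotonically
#' non-increasing, otherwise `weight` times the sum of squared violations
#' (bound violations, non-monotone dense time coordinate, and positive
#' increments of the sampled residue).
#'
#' @param points a [control_points] object (or numeric 5-vector).
#' @param residue the sampled residue [uniform_curve] (e.g. from
#'   [residue_from_controls]); monotonicity of its samples is penalized.
#' @param weight penalty weight (default `1e6`).
#' @return A non-negative scalar.
#' @export
constraint_penalty <- function(points, residue = NULL, weight = 1e6) {
  ctrl <- as_ctrl(points)
  p1x <- ctrl[1]; p1y <- ctrl[2]; p2x <- ctrl[3]; p2y <- ctrl[4]; p3x <- ctrl[5]
  pen <- 0
  p3e <- max(p3x, 0.1)
  if (p3x < 0.1) pen <- pen + (0.1 - p3x)^2
  pen <- pen + min(p1y, 0)^2 + max(p1y - 1, 0)^2
  pen <- pen + min(p2y, 0)^2 + max(p2y - 1, 0)^2
  pen <- pen + min(p1x, 0)^2 + max(p1x - p3e, 0)^2
  pen <- pen + min(p2x, 0)^2 + max(p2x - p3e, 0)^2
  if (p3x > 0) {
    dense <- bezier_eval(ctrl, seq(0, 1, length.out = 2001))
    pen <- pen + sum(pmin(diff(dense$x), 0)^2)
  }
  if (!is.null(residue)) {
    stopifnot(inherits(residue, "uniform_curve"))
    pen <- pen + sum(pmax(diff(residue$values), 0)^2)
  }
  weight * pen
}
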