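#' Simulation configuration
#'
#' Describes one simulated DSC-MRI study condition: baseline SNR, residue
#' shape, blood volume, the CBF grid, delay/dispersion distortion of the
#' arterial input and the replicate count. Defaults reproduce the standard
#' study conditions: TR 1.24 s over a 200 s record, TE 29 ms, baseline signal
#' 100, bolus arrival 20 s, CBV 4% with CBF 10-70 ml/100 g/min.
#'
#' @param snr baseline SNR (pre-bolus signal amplitude over noise sd); `Inf`
#'   for noiseless curves.
#' @param lam residue shape parameter \eqn{\lambda} of the gamma family
#'   (1 = exponential, 5 = sigmoid, 100 = boxcar).
#' @param cbv blood volume fraction (0.04 or 0.02).
#' @param cbf_grid CBF levels in ml/100 g/min.
#' @param delta arterial delay of the tissue input (s).
#' @param dispersion `list(kind = "none")`, `list(kind = "exponential",
#'   theta = ...)` or `list(kind = "gamma", s = ..., p = ...)`.
#' @param n_reps noisy replicates per CBF level.
#' @param seed master RNG seed; per-voxel substreams are derived from
#'   `(seed, condition, CBF index, replicate index)` so that scaled-down runs
#'   are prefix-consistent with full runs.
#' @param tr,duration,te,s0,t0 acquisition constants: sampling interval (s),
#'   record length (s), echo time (s), baseline signal, bolus arrival (s).
#' @param aif_noise add Rician noise to the arterial signal as well as the
#'   tissue signal (the default); `FALSE` keeps the measured AIF noise-free.
#' @param condition_id optional integer tag entering the per-voxel seed;
#'   studies that pair replicates across distortion levels set the same id
#'   for every level so that noise realizations match.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(snr = 20, lam = 1, cbv = 0.04,
                       cbf_grid = seq(10, 70, by = 10), delta = 0,
                       dispersion = list(kind = "none"), n_reps = 64,
                       seed = 20220113, tr = 1.24, duration = 200,
                       te = 0.029, s0 = 100, t0 = 20, aif_noise = TRUE,
                       condition_id = NULL) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (cbv <= 0 || cbv >= 1) stop("cbv must be in (0, 1)", call. = FALSE)
  if (!dispersion$kind %in% c("none", "exponential", "gamma"))
    stop(sprintf("unknown dispersion kernel '%s'", dispersion$kind),
         call. = FALSE)
  cfg <- list(snr = snr, lam = lam, cbv = cbv, cbf_grid = cbf_grid,
              delta = delta, dispersion = dispersion, n_reps = n_reps,
              seed = as.integer(seed), tr = tr, duration = duration,
              te = te, s0 = s0, t0 = t0, aif_noise = isTRUE(aif_noise),
              condition_id = condition_id)
  class(cfg) <- "sim_config"
  cfg
}

# internal: time grid for a config
config_grid <- function(config) {
  n <- floor(config$duration / config$tr) + 1L
  uniform_curve(numeric(n), dt = config$tr, t0 = 0)
}

# internal: small integer hash of the condition for seed derivation
condition_hash <- function(config) {
  if (!is.null(config$condition_id)) return(as.integer(config$condition_id))
  key <- paste(config$snr, config$lam, config$cbv, config$delta,
               config$dispersion$kind,
               paste(unlist(config$dispersion[-1]), collapse = ","),
               sep = "|")
  sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 31 + 1)) %% 100003L
}

#' Gamma-variate arterial input function
#'
#' \eqn{C_a(t) = a (t - t_0)^b e^{-(t - t_0)/c}} for \eqn{t > t_0}, zero
#' before bolus arrival. With the default shape (`a = 1, b = 3, c = 1.5`)
#' the continuous peak sits at \eqn{t_0 + bc = 24.5} s.
#'
#' @param grid a [uniform_curve] supplying the output grid.
#' @param t0 bolus arrival time (s).
#' @param a,b,c gamma-variate shape constants.
#' @return A [uniform_curve] with the AIF.
#' @export
gamma_variate_aif <- function(grid, t0 = 20, a = 1, b = 3, c = 1.5) {
  stopifnot(inherits(grid, "uniform_curve"))
  tt <- curve_time(grid)
  v <- ifelse(tt <= t0, 0, a * (tt - t0)^b * exp(-(tt - t0) / c))
  uniform_curve(v, dt = grid$dt, t0 = grid$t0)
}

#' Gamma-family residue function
#'
#' Upper-tail probability of a gamma distribution with shape \eqn{\lambda}
#' and scale \eqn{\beta = MTT/\lambda}:
#' \eqn{R(t) = P(T > t)} for transit times \eqn{T \sim
#' \Gamma(\lambda, \beta)}. \eqn{\lambda = 1} gives the exponential
#' \eqn{e^{-t/MTT}}, \eqn{\lambda = 5} a sigmoid and \eqn{\lambda = 100} an
#' approximate boxcar. \eqn{R(0) = 1}, monotone non-increasing, and
#' \eqn{\int_0^\infty R = MTT} for every \eqn{\lambda}.
#'
#' @param lam shape parameter, positive.
#' @param mtt mean transit time (s), positive.
#' @param grid a [uniform_curve] supplying the output grid.
#' @return A [uniform_curve] with the residue function.
#' @export
gamma_residue <- function(lam, mtt, grid) {
  stopifnot(inherits(grid, "uniform_curve"))
  if (lam <= 0 || mtt <= 0) stop("lam and mtt must be positive", call. = FALSE)
  tt <- curve_time(grid) - grid$t0
  v <- stats::pgamma(tt, shape = lam, scale = mtt / lam, lower.tail = FALSE)
  uniform_curve(v, dt = grid$dt, t0 = 0)
}

#' Exponential dispersion kernel
#'
#' \eqn{EDK(t) = e^{-t/\theta}/\theta}, renormalized to unit discrete area.
#' Used to disperse the simulated AIF with a kernel family different from the
#' gamma transport function employed in the fitting model;
#' \eqn{\theta \in \{1.5, 3.0, 4.5\}} model low/medium/high dispersion.
#'
#' @param theta kernel time constant (s), positive.
#' @param grid a [uniform_curve] supplying the output grid.
#' @return A [uniform_curve] with the kernel.
#' @export
exponential_dispersion_kernel <- function(theta, grid) {
  stopifnot(inherits(grid, "uniform_curve"))
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  tt <- curve_time(grid) - grid$t0
  v <- exp(-tt / theta) / theta
  v <- v / (sum(v) * grid$dt)
  uniform_curve(v, dt = grid$dt, t0 = 0)
}

#' Delay the analytic AIF on a high-resolution grid
#'
#' The gamma-variate AIF is evaluated at a 100-ms sampling interval, shifted
#' by `delta`, and resampled to the acquisition grid by cubic-spline
#' interpolation, so that sub-TR delays are represented accurately (exact,
#' up to spline error, for any `delta`; a delay of \eqn{\delta} is identical
#' to moving the bolus arrival to \eqn{t_0 + \delta}).
#'
#' @param grid acquisition grid (a [uniform_curve]).
#' @param delta delay in seconds.
#' @param t0,a,b,c analytic AIF parameters, see [gamma_variate_aif].
#' @return A [uniform_curve] with the delayed AIF on the acquisition grid.
#' @export
apply_delay_highres <- function(grid, delta, t0 = 20, a = 1, b = 3,
                                c = 1.5) {
  stopifnot(inherits(grid, "uniform_curve"))
  tt <- curve_time(grid)
  fine_dt <- 0.1
  fine_t <- seq(0, max(tt) + fine_dt, by = fine_dt)
  fine_v <- ifelse(fine_t <= t0, 0,
                   a * (fine_t - t0)^b * exp(-(fine_t - t0) / c))
  k <- round(delta / fine_dt)
  nf <- length(fine_v)
  if (abs(k) >= nf) {
    shifted <- numeric(nf)
  } else if (k >= 0) {
    shifted <- c(numeric(k), fine_v[seq_len(nf - k)])
  } else {
    shifted <- c(fine_v[(-k + 1):nf], numeric(-k))
  }
  f <- stats::splinefun(fine_t, shifted, method = "natural")
  uniform_curve(pmax(f(tt), 0), dt = grid$dt, t0 = grid$t0)
}

#' Calibrate the concentration-to-signal constants
#'
#' Solves for the signal-model constants \eqn{\xi} such that (i) the
#' noiseless reference tissue signal (exponential residue, CBF
#' 60 ml/100 g/min, CBV 4%) exhibits a peak signal drop of 40% of the
#' baseline, and (ii) the arterial signal drops by 60%. Closed form:
#' \eqn{\xi = -\ln(1 - drop) / (TE \cdot \max C)}.
#'
#' @param grid acquisition grid (a [uniform_curve]).
#' @param te echo time (s).
#' @param t0 bolus arrival time (s).
#' @return A list with `xi_tissue` and `xi_aif`.
#' @export
calibrate_xi <- function(grid, te = 0.029, t0 = 20) {
  stopifnot(inherits(grid, "uniform_curve"))
  aif <- gamma_variate_aif(grid, t0 = t0)
  Rref <- gamma_residue(lam = 1, mtt = 4, grid = grid)
  ctc <- forward_model(aif, Rref, cbf = 60 / CBF_TO_CLINICAL, kappa = 1)
  list(xi_tissue = -log(1 - 0.40) / (te * max(ctc$values)),
       xi_aif = -log(1 - 0.60) / (te * max(aif$values)))
}

#' Add Rician noise to a signal curve
#'
#' Magnitude-image noise model: each output sample is
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with \eqn{n_1, n_2} independent
#' zero-mean Gaussians of standard deviation \eqn{\sigma = S_0 / SNR}
#' (baseline SNR convention). Draws come from the current RNG state.
#'
#' @param signal a [uniform_curve] of signal values.
#' @param snr baseline SNR; `Inf` returns the input unchanged.
#' @param s0 baseline signal defining \eqn{\sigma}.
#' @return A noisy [uniform_curve].
#' @export
add_rician_noise <- function(signal, snr, s0 = 100) {
  stopifnot(inherits(signal, "uniform_curve"))
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (!is.finite(snr)) return(signal)
  sigma <- s0 / snr
  n <- length(signal$values)
  n1 <- stats::rnorm(n, sd = sigma)
  n2 <- stats::rnorm(n, sd = sigma)
  uniform_curve(sqrt((signal$values + n1)^2 + n2^2),
                dt = signal$dt, t0 = signal$t0)
}

#' Simulate a DSC-MRI dataset
#'
#' For each CBF level and replicate: build the truth residue function, apply
#' the configured delay and/or dispersion to the arterial input feeding the
#' tissue, form the noiseless tissue curve through the forward model
#' (\eqn{\kappa = 1}), convert tissue curve and (undistorted, "measured")
#' AIF to signal, add Rician noise to both signals, and convert back to
#' concentration using the baseline estimated from the pre-bolus samples.
#' The known calibration constants \eqn{\xi} are divided out on
#' back-conversion so tissue and arterial curves share the generating
#' concentration scale. Fully deterministic given `(seed, condition,
#' replicate index)`.
#'
#' @param config a [sim_config].
#' @return A list of class `sim_dataset` with elements `config`, `grid`,
#'   `aif_clean` (noiseless measured AIF), `truth` (data frame with one row
#'   per voxel: cbf, cbv, mtt, delay, dispersion parameters, seeds) and
#'   `voxels` (list with per-voxel `ctc`, `aif`, `residue_truth`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config_grid(config)
  aif_clean <- gamma_variate_aif(grid, t0 = config$t0)
  # arterial input actually feeding the tissue (delayed / dispersed)
  aif_input <- if (config$delta != 0)
    apply_delay_highres(grid, config$delta, t0 = config$t0) else aif_clean
  disp <- config$dispersion
  if (disp$kind == "exponential") {
    aif_input <- convolve_uniform(
      aif_input, exponential_dispersion_kernel(disp$theta, grid))
  } else if (disp$kind == "gamma") {
    aif_input <- convolve_uniform(aif_input, gamma_vtf(disp$s, disp$p, grid))
  }
  xi <- calibrate_xi(grid, te = config$te, t0 = config$t0)
  aif_signal <- concentration_to_signal(aif_clean, config$s0, config$te,
                                        xi$xi_aif)
  chash <- condition_hash(config)
  baseline_idx <- which(curve_time(grid) < config$t0)
  consts <- acquisition_constants(te = config$te, tr = config$tr,
                                  s0 = config$s0, kappa = 1)

  voxels <- vector("list", length(config$cbf_grid) * config$n_reps)
  truth <- vector("list", length(voxels))
  v <- 0L
  for (ci in seq_along(config$cbf_grid)) {
    cbf_clin <- config$cbf_grid[ci]
    cbf <- cbf_clin / CBF_TO_CLINICAL
    mtt <- config$cbv / cbf
    residue <- gamma_residue(config$lam, mtt, grid)
    ctc_clean <- forward_model(aif_input, residue, cbf, kappa = 1)
    ctc_signal <- concentration_to_signal(ctc_clean, config$s0, config$te,
                                          xi$xi_tissue)
    for (rep in seq_len(config$n_reps)) {
      v <- v + 1L
      vseed <- (config$seed + 100003 * chash + 2048 * ci + rep) %% 2147483647
      set.seed(vseed)
      s_noisy <- add_rician_noise(ctc_signal, config$snr, s0 = config$s0)
      sa_noisy <- if (config$aif_noise)
        add_rician_noise(aif_signal, config$snr, s0 = config$s0)
      else aif_signal
      ctc_noisy <- recover_concentration(s_noisy, baseline_idx, consts,
                                         xi$xi_tissue)
      aif_noisy <- recover_concentration(sa_noisy, baseline_idx, consts,
                                         xi$xi_aif)
      voxels[[v]] <- list(ctc = ctc_noisy, aif = aif_noisy,
                          residue_truth = residue,
                          signal = s_noisy, aif_signal = sa_noisy)
      truth[[v]] <- data.frame(voxel = v, cbf_index = ci, rep = rep,
                               cbf_ml100gmin = cbf_clin, cbf = cbf,
                               cbv = config$cbv, mtt = mtt,
                               delay = config$delta,
                               dispersion = disp$kind, seed = vseed)
    }
  }
  structure(list(config = config, grid = grid, aif_clean = aif_clean,
                 xi = xi, truth = do.call(rbind, truth), voxels = voxels),
            class = "sim_dataset")
}

# internal: noisy signal -> concentration on the generating scale
recover_concentration <- function(signal, baseline_idx, consts, xi) {
  s0_hat <- mean(signal$values[baseline_idx])
  conc <- -log(signal$values / s0_hat) / consts$te
  uniform_curve(conc / xi, dt = signal$dt, t0 = signal$t0)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "simulated DSC-MRI dataset: %d voxels (%d CBF levels x %d reps)\n",
    length(x$voxels), length(cfg$cbf_grid), cfg$n_reps))
  cat(sprintf("  SNR %g, lambda %g, CBV %g%%, delay %g s, dispersion %s\n",
              cfg$snr, cfg$lam, 100 * cfg$cbv, cfg$delta,
              cfg$dispersion$kind))
  invisible(x)
}
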