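#' Discrete particle size distribution
#'
#' A PSD on a strictly increasing diameter grid with normalised non-negative
#' weights under one of three weightings: `intensity` (scattered-intensity
#' weighted, proportional to d^6 times number in the Rayleigh regime),
#' `number` (per-particle), or `volume` (proportional to d^3 times number).
#'
#' @param diameters Strictly increasing positive grid, nm.
#' @param weights Non-negative weights; normalised to sum to 1.
#' @param weighting `"intensity"`, `"number"` or `"volume"`.
#' @return Object of class `"size_distribution"`.
#' @export
size_distribution <- function(diameters, weights,
                              weighting = c("intensity", "number", "volume")) {
  weighting <- match.arg(weighting)
  if (!is.numeric(diameters) || any(diameters <= 0) ||
      any(diff(diameters) <= 0)) {
    stop("`diameters` must be a strictly increasing positive grid")
  }
  if (!is.numeric(weights) || length(weights) != length(diameters) ||
      any(weights < 0) || any(!is.finite(weights))) {
    stop("`weights` must be non-negative, finite, same length as grid")
  }
  tot <- sum(weights)
  if (tot == 0) stop("degenerate distribution: all weights zero")
  if (abs(tot - 1) > 1e-6) {
    warning("weights did not sum to 1; normalising")
  }
  structure(list(diameters = as.numeric(diameters),
                 weights = as.numeric(weights) / tot,
                 weighting = weighting),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Size distribution (%s-weighted), %d grid points\n",
              x$weighting, length(x$diameters)))
  cat(sprintf("  grid  : %.4g .. %.4g nm\n",
              min(x$diameters), max(x$diameters)))
  cat(sprintf("  mode  : %.4g nm; weighted mean %.4g nm\n",
              psd_mode(x), sum(x$weights * x$diameters)))
  invisible(x)
}

#' Lognormal PSD on a discrete grid
#'
#' @param meanlog,sdlog Log-scale parameters of the lognormal.
#' @param weighting Weighting tag attached to the distribution.
#' @param n Number of grid points.
#' @param span Grid half-width in units of `sdlog` around `meanlog`.
#' @return A [size_distribution()].
#' @export
lognormal_psd <- function(meanlog, sdlog,
                          weighting = c("intensity", "number", "volume"),
                          n = 501L, span = 5) {
  weighting <- match.arg(weighting)
  g <- exp(seq(meanlog - span * sdlog, meanlog + span * sdlog,
               length.out = n))
  w <- stats::dnorm(log(g), meanlog, sdlog)
  size_distribution(g, w / sum(w), weighting)
}

#' Intensity-weighted PSD matching a cumulant target
#'
#' Constructs the lognormal intensity-weighted PSD whose intensity-weighted
#' harmonic mean diameter equals `z_ave` and whose normalised decay-rate
#' variance equals `pdi`: with intensity-weighted diameters lognormal
#' (m, s), s^2 = log(1 + pdi) and m = log(z_ave) + s^2/2.
#'
#' @param z_ave Target Z-average diameter, nm.
#' @param pdi Target polydispersity index (>= 0).
#' @inheritParams lognormal_psd
#' @return An intensity-weighted [size_distribution()].
#' @export
calibrate_intensity_psd <- function(z_ave, pdi, n = 501L, span = 5) {
  .assert_scalar_pos(z_ave, "z_ave")
  if (pdi < 0) stop("`pdi` must be >= 0")
  if (pdi == 0) {
    # monodisperse limit: single grid point
    return(size_distribution(z_ave, 1, "intensity"))
  }
  s2 <- log(1 + pdi)
  lognormal_psd(log(z_ave) + s2 / 2, sqrt(s2), "intensity", n, span)
}

#' DLS instrument parameters
#'
#' Defaults follow a 173-degree backscatter measurement in water at 4 degrees
#' Celsius with a 633 nm He-Ne laser (viscosity 1.567 mPa s, refractive
#' index 1.333).
#'
#' @param angle_deg Detection angle, degrees (0, 180].
#' @param wavelength_nm Laser vacuum wavelength, nm.
#' @param temperature_K Absolute temperature, K.
#' @param viscosity_mPas Dispersant dynamic viscosity, mPa s.
#' @param refractive_index Dispersant refractive index.
#' @return List of class `"dls_instrument"`.
#' @export
dls_instrument <- function(angle_deg = 173, wavelength_nm = 633,
                           temperature_K = 277.15, viscosity_mPas = 1.567,
                           refractive_index = 1.333) {
  .assert_scalar_pos(temperature_K, "temperature_K")
  .assert_scalar_pos(viscosity_mPas, "viscosity_mPas")
  .assert_scalar_pos(wavelength_nm, "wavelength_nm")
  if (angle_deg <= 0 || angle_deg > 180) {
    stop("`angle_deg` must lie in (0, 180]")
  }
  structure(list(angle_deg = angle_deg, wavelength_nm = wavelength_nm,
                 temperature_K = temperature_K,
                 viscosity_mPas = viscosity_mPas,
                 refractive_index = refractive_index),
            class = "dls_instrument")
}

.kB <- 1.380649e-23  # J/K

#' Stokes-Einstein translational diffusion coefficient
#'
#' D = kT / (3 pi eta d) for a sphere of hydrodynamic diameter d.
#'
#' @param diameter_nm Hydrodynamic diameter, nm. Vectorised.
#' @param temperature_K Absolute temperature, K.
#' @param viscosity_mPas Dynamic viscosity, mPa s.
#' @return Diffusion coefficient, m^2/s.
#' @examples
#' stokes_einstein_diffusion(100, 298.15, 0.89)  # ~4.91e-12
#' @export
stokes_einstein_diffusion <- function(diameter_nm, temperature_K,
                                      viscosity_mPas) {
  if (any(diameter_nm <= 0)) stop("`diameter_nm` must be positive")
  .assert_scalar_pos(temperature_K, "temperature_K")
  .assert_scalar_pos(viscosity_mPas, "viscosity_mPas")
  .kB * temperature_K /
    (3 * pi * viscosity_mPas * 1e-3 * diameter_nm * 1e-9)
}

#' Scattering vector magnitude
#'
#' q = (4 pi n / lambda) sin(theta / 2).
#'
#' @param wavelength_nm Laser vacuum wavelength, nm.
#' @param refractive_index Dispersant refractive index.
#' @param angle_deg Detection angle, degrees (0, 180].
#' @return q in 1/m.
#' @examples
#' scattering_vector(633, 1.333, 173)  # ~2.64e7
#' @export
scattering_vector <- function(wavelength_nm, refractive_index, angle_deg) {
  .assert_scalar_pos(wavelength_nm, "wavelength_nm")
  .assert_scalar_pos(refractive_index, "refractive_index")
  if (angle_deg <= 0 || angle_deg > 180) {
    stop("`angle_deg` must lie in (0, 180]")
  }
  4 * pi * refractive_index / (wavelength_nm * 1e-9) *
    sin(angle_deg / 2 * pi / 180)
}

#' Simulate a DLS intensity autocorrelation function
#'
#' Generates g2(tau) = 1 + beta [sum_i w_i exp(-q^2 D_i tau)]^2 + noise,
#' where w_i are the PSD's intensity weights, D_i the Stokes-Einstein
#' diffusion coefficients and q the scattering vector. A number- or
#' volume-weighted PSD is converted to intensity weighting first.
#'
#' @param psd A [size_distribution()].
#' @param instrument A [dls_instrument()].
#' @param beta Coherence (intercept) factor in (0, 1].
#' @param noise_sd SD of additive Gaussian noise on g2 (0 for a noiseless
#'   curve).
#' @param lag_grid Positive increasing lag times, seconds; default 250
#'   log-spaced lags from 1 microsecond to 0.1 s.
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @return Object of class `"correlogram"`: list with `lag_s`, `g2`,
#'   `instrument`, `beta`, `noise_sd`.
#' @export
simulate_correlogram <- function(psd, instrument = dls_instrument(),
                                 beta = 0.8, noise_sd = 0,
                                 lag_grid = NULL, seed = 1L) {
  stopifnot(inherits(psd, "size_distribution"),
            inherits(instrument, "dls_instrument"))
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]")
  if (is.null(lag_grid)) {
    lag_grid <- exp(seq(log(1e-6), log(1e-1), length.out = 250L))
  }
  if (any(lag_grid <= 0) || any(diff(lag_grid) <= 0)) {
    stop("`lag_grid` must be positive and increasing")
  }
  if (psd$weighting != "intensity") psd <- reweight_psd(psd, "intensity")
  Gam <- scattering_vector(instrument$wavelength_nm,
                           instrument$refractive_index,
                           instrument$angle_deg)^2 *
    stokes_einstein_diffusion(psd$diameters, instrument$temperature_K,
                              instrument$viscosity_mPas)
  g1 <- vapply(lag_grid, function(t) sum(psd$weights * exp(-Gam * t)),
               numeric(1))
  g2 <- 1 + beta * g1^2
  if (noise_sd > 0) {
    g2 <- g2 + local_seed(seed, stats::rnorm(length(g2), 0, noise_sd))
  }
  structure(list(lag_s = lag_grid, g2 = g2, instrument = instrument,
                 beta = beta, noise_sd = noise_sd),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("DLS correlogram: %d lags, %.2g .. %.2g s (beta %.2f, noise %g)\n",
              length(x$lag_s), min(x$lag_s), max(x$lag_s), x$beta, x$noise_sd))
  invisible(x)
}

#' Second-order cumulant analysis of a DLS correlogram
#'
#' Fits the standard second-order cumulant expansion
#' \eqn{\ln[(g_2(\tau)-1)/\beta]/2 \approx -\bar\Gamma \tau +
#' (\mu_2/2)\tau^2} by amplitude-weighted least squares over the lags where
#' \eqn{(g_2-1)/\beta \ge} `window_floor` (avoiding log-noise blow-up in the
#' far tail). The Z-average diameter is the mean decay rate mapped through
#' the scattering vector and the Stokes-Einstein relation (the
#' intensity-weighted harmonic mean diameter); PDI = \eqn{\mu_2/\bar\Gamma^2},
#' clamped at 0 (with `pdi_clamped = TRUE`) when the quadratic coefficient
#' fits negative.
#'
#' @param correlogram A [simulate_correlogram()] result or any object with
#'   `lag_s`, `g2` and `instrument`; `beta` is taken from the object when
#'   present, otherwise estimated from the fit intercept.
#' @param window_floor Fraction of the normalised correlation amplitude kept
#'   in the fit window (default 0.1).
#' @return Object of class `"cumulant_fit"` with `z_ave` (nm), `pdi`,
#'   `gamma_bar` (1/s), `mu2` (1/s^2), `fit_rmse` (weighted residual scale),
#'   `pdi_clamped`, `n_lags`, plus the fit window, fitted values and
#'   residuals (accessible via [coef()], [fitted()] and [residuals()]
#'   methods).
#' @export
cumulant_fit <- function(correlogram, window_floor = 0.1) {
  stopifnot(inherits(correlogram, "correlogram"))
  tau <- correlogram$lag_s
  amp <- correlogram$g2 - 1
  beta <- correlogram$beta
  if (is.null(beta)) beta <- max(amp)
  norm <- amp / beta
  win <- which(norm >= window_floor)
  if (length(win) < 3L || any(norm[win] <= 0)) {
    stop("fit failure: correlogram does not decay over a usable window")
  }
  if (any(diff(amp[win]) > 1e-9 * max(amp))) {
    # monotone decay is expected of a correlation function at low noise;
    # mild noise is tolerated, gross growth is not
    if (stats::cor(tau[win], amp[win]) > 0) {
      stop("fit failure: correlogram does not decay (g2 increases with lag)")
    }
  }
  y <- 0.5 * log(norm[win])
  X <- cbind(1, -tau[win], tau[win]^2 / 2)
  w <- norm[win]^2  # amplitude weighting stabilises the linearised fit
  fit <- stats::lm.wfit(X, y, w)
  co <- fit$coefficients
  gamma_bar <- co[[2]]
  mu2 <- co[[3]]
  if (!is.finite(gamma_bar) || gamma_bar <= 0) {
    stop("fit failure: non-positive mean decay rate")
  }
  ins <- correlogram$instrument
  q <- scattering_vector(ins$wavelength_nm, ins$refractive_index,
                         ins$angle_deg)
  Dbar <- gamma_bar / q^2
  z_ave <- .kB * ins$temperature_K / (3 * pi * ins$viscosity_mPas * 1e-3 *
                                        Dbar) * 1e9
  pdi <- mu2 / gamma_bar^2
  clamped <- FALSE
  if (pdi < 0) {
    pdi <- 0
    clamped <- TRUE
  }
  rmse <- sqrt(sum(w * fit$residuals^2) / sum(w))
  structure(
    list(z_ave = z_ave, pdi = pdi, gamma_bar = gamma_bar, mu2 = mu2,
         fit_rmse = rmse, pdi_clamped = clamped, n_lags = length(win),
         window = win, lag_s = tau[win], y = y, fitted = fit$fitted.values,
         residuals = fit$residuals, weights = w, beta = beta),
    class = "cumulant_fit"
  )
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat("Second-order cumulant fit\n")
  cat(sprintf("  Z-average : %.2f nm\n", x$z_ave))
  cat(sprintf("  PDI       : %.4f%s\n", x$pdi,
              if (x$pdi_clamped) " (clamped at 0)" else ""))
  cat(sprintf("  mean decay rate: %.4g 1/s over %d lags (rmse %.2g)\n",
              x$gamma_bar, x$n_lags, x$fit_rmse))
  invisible(x)
}

#' @export
coef.cumulant_fit <- function(object, ...) {
  c(z_ave = object$z_ave, pdi = object$pdi,
    gamma_bar = object$gamma_bar, mu2 = object$mu2)
}

#' @export
fitted.cumulant_fit <- function(object, ...) object$fitted

#' @export
residuals.cumulant_fit <- function(object, ...) object$residuals

#' @export
summary.cumulant_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Convert a PSD between intensity, number and volume weighting
#'
#' Rayleigh-regime conversions: intensity weight is proportional to number
#' weight times d^6 and volume weight to number weight times d^3. The grid
#' is unchanged; weights are renormalised.
#'
#' @param psd A [size_distribution()].
#' @param target Target weighting.
#' @return A [size_distribution()] with the requested weighting.
#' @export
reweight_psd <- function(psd, target = c("intensity", "number", "volume")) {
  stopifnot(inherits(psd, "size_distribution"))
  target <- match.arg(target)
  if (target == psd$weighting) return(psd)
  pow <- c(number = 0, volume = 3, intensity = 6)
  w <- psd$weights * psd$diameters^(pow[[target]] - pow[[psd$weighting]])
  if (sum(w) == 0 || !all(is.finite(w))) {
    stop("degenerate distribution after reweighting")
  }
  size_distribution(psd$diameters, w / sum(w), target)
}

#' Mode of a discrete PSD
#'
#' Grid point of maximum weight density (weight divided by the local grid
#' spacing, so the answer does not depend on whether the grid is linear or
#' logarithmic); ties resolve to the smallest diameter.
#'
#' @param psd A [size_distribution()].
#' @return Diameter at maximum weight density, nm.
#' @export
psd_mode <- function(psd) {
  stopifnot(inherits(psd, "size_distribution"))
  d <- psd$diameters
  if (length(d) == 1L) return(d)
  # midpoint cell widths; end cells take the adjacent interval
  width <- c(d[2] - d[1], (d[-(1:2)] - d[seq_len(length(d) - 2L)]) / 2,
             d[length(d)] - d[length(d) - 1L])
  d[which.max(psd$weights / width)]
}
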