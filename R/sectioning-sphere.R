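#' Sectioning model for a spherical particle
#'
#' Describes how an ultra-thin section samples a sphere of true diameter
#' `D_actual`. A microtome section at distance `r` from the sphere centre
#' exposes a circle of diameter \eqn{d(r) = 2\sqrt{(D/2)^2 - r^2}}, so any
#' random-sectioning protocol reports diameters below the true one. Two
#' sampling schemes are supported:
#'
#' * `"volume_weighted"`: the section position is weighted by the spherical
#'   volume element (density proportional to \eqn{r^2} on \eqn{[0, D/2]}).
#'   Its expectation is \eqn{(3\pi/16)\,D}, i.e. ~41\% underestimation.
#' * `"uniform_plane"`: the classical stereological convention of a uniformly
#'   random plane offset, with expectation \eqn{(\pi/4)\,D} (~21.5\%
#'   underestimation).
#'
#' `detection_limit` models the practical inability to recognise the smallest
#' sections during image analysis: sections with apparent diameter below the
#' limit are discarded, which raises the mean of the recorded diameters.
#'
#' @param D_actual True sphere diameter in nm (> 0).
#' @param scheme Section-position sampling scheme, `"volume_weighted"`
#'   (default) or `"uniform_plane"`.
#' @param slice_thickness Physical section thickness in nm (>= 0). The default
#'   0 is the infinitesimal-section model used throughout; a finite value is
#'   honoured by the Monte-Carlo sampler (max diameter over the slab) but has
#'   no analytic branch.
#' @param detection_limit Minimum recordable section diameter in nm
#'   (0 <= detection_limit <= D_actual).
#'
#' @return An object of class `"sectioning_model"`.
#' @seealso [expected_section_diameter()], [mc_section_sphere()],
#'   [fit_detection_limit()]
#' @examples
#' m <- sectioning_model(138)
#' expected_section_diameter(m)     # 3*pi/16 * 138
#' underestimation_percent(m)       # ~41.1
#' @export
sectioning_model <- function(D_actual,
                             scheme = c("volume_weighted", "uniform_plane"),
                             slice_thickness = 0,
                             detection_limit = 0) {
  scheme <- match.arg(scheme)
  if (!is.numeric(D_actual) || length(D_actual) != 1L || !is.finite(D_actual) ||
      D_actual <= 0) {
    stop("`D_actual` must be a single positive finite number (nm)")
  }
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      slice_thickness < 0) {
    stop("`slice_thickness` must be a single non-negative number (nm)")
  }
  if (!is.numeric(detection_limit) || length(detection_limit) != 1L ||
      detection_limit < 0) {
    stop("`detection_limit` must be a single non-negative number (nm)")
  }
  if (detection_limit > D_actual) {
    stop("`detection_limit` must not exceed `D_actual`")
  }
  structure(
    list(D_actual = D_actual, scheme = scheme,
         slice_thickness = slice_thickness, detection_limit = detection_limit),
    class = "sectioning_model"
  )
}

#' @export
print.sectioning_model <- function(x, ...) {
  cat("Sphere sectioning model\n")
  cat(sprintf("  true diameter   : %g nm\n", x$D_actual))
  cat(sprintf("  sampling scheme : %s\n", x$scheme))
  cat(sprintf("  slice thickness : %g nm\n", x$slice_thickness))
  cat(sprintf("  detection limit : %g nm\n", x$detection_limit))
  if (x$detection_limit == 0 && x$slice_thickness == 0) {
    cat(sprintf("  E[apparent]     : %.4g nm (%.1f%% underestimation)\n",
                expected_section_diameter(x), underestimation_percent(x)))
  }
  invisible(x)
}

#' Diameter of a spherical cross-section at a given depth
#'
#' For a sphere of diameter `D`, a plane at distance `r` from the centre cuts
#' a circle of diameter \eqn{d(r) = D\sqrt{1 - (2r/D)^2}}.
#'
#' @param r Distance of the section plane from the sphere centre, nm
#'   (0 <= r <= D/2). Vectorised.
#' @param D Sphere diameter, nm (> 0).
#' @return Section diameter(s) in nm.
#' @examples
#' section_diameter_at(0, 100)   # equatorial: 100
#' section_diameter_at(25, 100)  # 100*sqrt(3)/2
#' @export
section_diameter_at <- function(r, D) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0) {
    stop("`D` must be a single positive number (nm)")
  }
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > D / 2)) {
    stop("`r` must lie in [0, D/2]")
  }
  D * sqrt(pmax(0, 1 - (2 * r / D)^2))
}

#' Expected apparent diameter under sectioning (analytic branch)
#'
#' Closed-form expectation of the recorded section diameter:
#' \eqn{(3\pi/16)\,D} for the volume-weighted scheme (averaging \eqn{d(r)}
#' over the sphere volume) and \eqn{(\pi/4)\,D} for a uniform random plane
#' offset. Only the untruncated, zero-thickness model has a closed form; for
#' a nonzero `detection_limit` use [truncated_section_mean()] or
#' [mc_section_sphere()].
#'
#' @param model A [sectioning_model()].
#' @return Expected apparent diameter, nm.
#' @export
expected_section_diameter <- function(model) {
  stopifnot(inherits(model, "sectioning_model"))
  if (model$detection_limit != 0 || model$slice_thickness != 0) {
    stop("analytic expectation requires detection_limit = 0 and ",
         "slice_thickness = 0; use truncated_section_mean() or Monte Carlo")
  }
  switch(model$scheme,
         volume_weighted = 3 * pi / 16 * model$D_actual,
         uniform_plane   = pi / 4 * model$D_actual)
}

#' Percent underestimation of the true diameter
#'
#' Returns \eqn{100\,(1 - E[\mathrm{apparent}]/D)}; independent of the true
#' diameter. ~41.1 for the volume-weighted scheme, ~21.5 for uniform planes.
#'
#' @inheritParams expected_section_diameter
#' @return Underestimation in percent.
#' @export
underestimation_percent <- function(model) {
  100 * (1 - expected_section_diameter(model) / model$D_actual)
}

## scale-free truncated moments of the section-diameter distribution.
## u = detection_limit / D in [0, 1); returns E[d/D | d >= u*D].
.trunc_ratio <- function(u, scheme) {
  if (u >= 1) stop("truncation ratio must be < 1")
  R <- 0.5
  rt <- sqrt(pmax(0, R^2 - (u / 2)^2))  # sections at |r| <= rt survive
  w <- switch(scheme,
              volume_weighted = function(r) r^2,
              uniform_plane   = function(r) rep(1, length(r)))
  num <- stats::integrate(function(r) 2 * sqrt(pmax(0, R^2 - r^2)) * w(r),
                          0, rt, rel.tol = 1e-10)$value
  den <- stats::integrate(w, 0, rt, rel.tol = 1e-10)$value
  num / den
}

## probability that a section of a sphere with diameter D survives an
## absolute detection limit t, under the given scheme.
.accept_prob <- function(D, t, scheme) {
  u <- pmin(t / D, 1)
  frac <- sqrt(pmax(0, 1 - u^2))  # rt / R
  switch(scheme,
         volume_weighted = frac^3,
         uniform_plane   = frac)
}

#' Truncated expected section diameter
#'
#' Expected apparent diameter of a sectioned sphere conditional on the
#' section exceeding the model's detection limit, by numerical integration of
#' the analytic section-diameter density. Non-decreasing in the detection
#' limit and spans \eqn{[(3\pi/16)D, D)} (volume-weighted scheme) as the
#' limit spans \eqn{[0, D)}.
#'
#' @inheritParams expected_section_diameter
#' @return Truncated mean apparent diameter, nm.
#' @export
truncated_section_mean <- function(model) {
  stopifnot(inherits(model, "sectioning_model"))
  model$D_actual * .trunc_ratio(model$detection_limit / model$D_actual,
                                model$scheme)
}

#' Monte-Carlo sectioning of a sphere
#'
#' Draws `n` random section positions under the model's scheme
#' (volume-weighted: \eqn{r = (D/2)U^{1/3}}; uniform plane:
#' \eqn{r = (D/2)U}), evaluates the section diameter \eqn{d(r)}, and drops
#' values below the detection limit. With a nonzero `slice_thickness` the
#' recorded value is the largest circle diameter over the slab
#' \eqn{[r - h/2, r + h/2]} intersected with the sphere.
#'
#' @inheritParams expected_section_diameter
#' @param n Number of sections to draw (>= 1).
#' @param seed Integer RNG seed; every call is reproducible given the seed.
#' @return Numeric vector of recorded section diameters, nm. May be shorter
#'   than `n` (or empty, with a warning) after detection-limit filtering.
#' @export
mc_section_sphere <- function(model, n, seed) {
  stopifnot(inherits(model, "sectioning_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer")
  }
  n <- as.integer(n)
  R <- model$D_actual / 2
  d <- local_seed(seed, {
    u <- stats::runif(n)
    r <- switch(model$scheme,
                volume_weighted = R * u^(1 / 3),
                uniform_plane   = R * u)
    if (model$slice_thickness > 0) {
      # nearest point of the slab to the centre governs the widest circle
      r <- pmax(0, r - model$slice_thickness / 2)
    }
    section_diameter_at(pmin(r, R), model$D_actual)
  })
  d <- d[d >= model$detection_limit]
  if (length(d) == 0L) {
    warning("all sections fell below the detection limit; returning empty")
  }
  d
}

#' Fit the detection limit explaining an observed underestimation ratio
#'
#' Finds the left-truncation threshold at which the expected recorded section
#' diameter, divided by the true mean diameter, equals an observed ratio.
#' The objective is monotone in the threshold, so the root is bracketed and
#' found by bisection (absolute tolerance `1e-6 * D_actual`).
#'
#' With `true_size_sd = 0` the calculation is for a single sphere of diameter
#' `model$D_actual`. When the observed ratio is a population-level quantity
#' (a dataset mean over particles of varying true size), set `true_size_sd`
#' to the true-size standard deviation: the truncated mean and the
#' section-acceptance probability are then averaged over a normal true-size
#' distribution, which corrects the bias a fixed-diameter fit would incur.
#'
#' @param apparent_mean_ratio Observed mean apparent diameter divided by the
#'   (mean) true diameter; must lie between the untruncated ratio
#'   (3\eqn{\pi}/16 or \eqn{\pi}/4) and 1.
#' @param model A [sectioning_model()]; supplies the scheme and the (mean)
#'   true diameter.
#' @param true_size_sd Standard deviation of the true-diameter distribution,
#'   nm; 0 (default) for a single sphere.
#' @return Detection limit in nm.
#' @examples
#' m <- sectioning_model(138)
#' fit_detection_limit(3 * pi / 16, m)       # 0: no truncation needed
#' fit_detection_limit(99 / 138, m)          # single-sphere threshold
#' fit_detection_limit(99 / 138, m, true_size_sd = 21)  # population threshold
#' @export
fit_detection_limit <- function(apparent_mean_ratio, model, true_size_sd = 0) {
  stopifnot(inherits(model, "sectioning_model"))
  if (!is.numeric(apparent_mean_ratio) || length(apparent_mean_ratio) != 1L ||
      !is.finite(apparent_mean_ratio)) {
    stop("`apparent_mean_ratio` must be a single finite number")
  }
  base <- .trunc_ratio(0, model$scheme)
  if (apparent_mean_ratio < base - 1e-9 || apparent_mean_ratio >= 1) {
    stop(sprintf(
      "no detection limit can produce ratio %.4f (attainable range [%.4f, 1))",
      apparent_mean_ratio, base))
  }
  if (apparent_mean_ratio <= base + 1e-12) return(0)

  D <- model$D_actual
  objective <- if (true_size_sd <= 0) {
    function(t) .trunc_ratio(t / D, model$scheme) - apparent_mean_ratio
  } else {
    function(t) {
      .population_recorded_mean(t, D, true_size_sd, model$scheme) / D -
        apparent_mean_ratio
    }
  }
  upper <- D * (1 - 1e-9)
  stats::uniroot(objective, c(0, upper), tol = 1e-6 * D)$root
}

## expected recorded section diameter when true diameters are ~ N(mu, sd)
## (truncated at 0) and an absolute detection limit t applies: conditional
## on the section being recorded at all.
.population_recorded_mean <- function(t, mu, sd_, scheme) {
  lo <- max(t, 1e-9, mu - 8 * sd_)
  hi <- mu + 8 * sd_
  if (lo >= hi) return(0)
  num <- stats::integrate(function(D) {
    stats::dnorm(D, mu, sd_) * .accept_prob(D, t, scheme) *
      vapply(D, function(Dv) Dv * .trunc_ratio(min(t / Dv, 1 - 1e-12), scheme),
             numeric(1))
  }, lo, hi, rel.tol = 1e-8)$value
  den <- stats::integrate(function(D) {
    stats::dnorm(D, mu, sd_) * .accept_prob(D, t, scheme)
  }, lo, hi, rel.tol = 1e-8)$value
  num / den
}
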