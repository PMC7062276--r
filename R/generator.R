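#' Default per-technique sizing calibration
#'
#' The shipped calibration reproduces the pooled group statistics of the
#' five-technique MCP sizing comparison: negative-stain TEM 102 +/- 17 nm,
#' TEM after HMDS exchange 124 +/- 17 nm, SEM 126 +/- 17 nm, cryo-TEM
#' 138 +/- 21 nm, and ultra-thin-section (UTS) TEM 99 +/- 32 nm, each with
#' N = 300 measurements as 3 biological replicates of 100.
#'
#' @return Data frame with columns `technique`, `mean_nm`, `sd_nm`,
#'   `n_replicates`, `n_per_replicate`, `replicate_effect_sd_nm`.
#' @export
default_calibration <- function() {
  data.frame(
    technique = c("tem", "tem_hmds", "sem", "cryo", "uts"),
    mean_nm = c(102, 124, 126, 138, 99),
    sd_nm = c(17, 17, 17, 21, 32),
    n_replicates = 3L,
    n_per_replicate = 100L,
    replicate_effect_sd_nm = 5,
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic measurement generator
#'
#' Bundles the per-technique calibration table with the knobs of the
#' non-imaging generators (DLS/NTA) and the UTS generation mode.
#'
#' @param calibration Data frame as returned by [default_calibration()];
#'   columns `technique`, `mean_nm`, `sd_nm`, and optionally `n_replicates`
#'   (default 3), `n_per_replicate` (default 100), `replicate_effect_sd_nm`
#'   (default 5).
#' @param seed Default integer seed used when a generator call supplies none.
#' @param exact_moments If `TRUE` (default), each generated dataset is
#'   affinely standardised so its pooled mean and SD equal the calibration
#'   exactly; otherwise moments converge at rate 1/sqrt(N).
#' @param uts_mode `"direct"` draws UTS diameters from the calibrated
#'   (99, 32) normal like any other technique; `"sectioned"` derives them by
#'   stereological sectioning of true sizes (see
#'   [generate_uts_dataset_by_sectioning()]).
#' @param nta_mode_nm Mode of the main NTA lognormal population, nm.
#' @param nta_sigma Log-scale SD of the main NTA population.
#' @param nta_aggregate_fraction Probability that an NTA track belongs to the
#'   aggregate subpopulation, in \[0, 1).
#' @param nta_aggregate_mean_nm,nta_aggregate_sd_nm Mean and SD of the
#'   aggregate lognormal subpopulation, nm.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(calibration = default_calibration(),
                             seed = 1L,
                             exact_moments = TRUE,
                             uts_mode = c("direct", "sectioned"),
                             nta_mode_nm = 130.7,
                             nta_sigma = 0.15,
                             nta_aggregate_fraction = 0.03,
                             nta_aggregate_mean_nm = 400,
                             nta_aggregate_sd_nm = 100) {
  uts_mode <- match.arg(uts_mode)
  stopifnot(is.data.frame(calibration),
            all(c("technique", "mean_nm", "sd_nm") %in% names(calibration)))
  if (any(calibration$mean_nm <= 0) || any(calibration$sd_nm < 0)) {
    stop("calibration means must be positive and SDs non-negative")
  }
  if (is.null(calibration$n_replicates)) calibration$n_replicates <- 3L
  if (is.null(calibration$n_per_replicate)) calibration$n_per_replicate <- 100L
  if (is.null(calibration$replicate_effect_sd_nm)) {
    calibration$replicate_effect_sd_nm <- 5
  }
  if (nta_aggregate_fraction < 0 || nta_aggregate_fraction >= 1) {
    stop("`nta_aggregate_fraction` must lie in [0, 1)")
  }
  structure(
    list(calibration = calibration, seed = as.integer(seed),
         exact_moments = exact_moments, uts_mode = uts_mode,
         nta_mode_nm = nta_mode_nm, nta_sigma = nta_sigma,
         nta_aggregate_fraction = nta_aggregate_fraction,
         nta_aggregate_mean_nm = nta_aggregate_mean_nm,
         nta_aggregate_sd_nm = nta_aggregate_sd_nm),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic measurement generator configuration\n")
  cat(sprintf("  techniques    : %s\n",
              paste(x$calibration$technique, collapse = ", ")))
  cat(sprintf("  exact moments : %s; uts mode: %s; seed: %d\n",
              x$exact_moments, x$uts_mode, x$seed))
  invisible(x)
}

.cal_row <- function(config, technique) {
  i <- match(technique, config$calibration$technique)
  if (is.na(i)) {
    stop(sprintf("unknown technique '%s' (calibrated: %s)", technique,
                 paste(config$calibration$technique, collapse = ", ")))
  }
  config$calibration[i, ]
}

#' Per-technique diameter dataset
#'
#' A data frame of per-particle apparent diameters with columns `technique`,
#' `replicate` (integer id), `diameter_nm`; the container used by all sizing
#' statistics.
#'
#' @param technique Technique label.
#' @param replicate Integer replicate ids, recycled to the diameter length.
#' @param diameter_nm Positive diameters, nm.
#' @return Object of classes `"diameter_dataset"` and `"data.frame"`.
#' @export
diameter_dataset <- function(technique, replicate, diameter_nm) {
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0)) {
    stop("all diameters must be positive and finite")
  }
  d <- data.frame(technique = as.character(technique),
                  replicate = as.integer(replicate),
                  diameter_nm = as.numeric(diameter_nm),
                  stringsAsFactors = FALSE)
  class(d) <- c("diameter_dataset", "data.frame")
  d
}

#' Generate a calibrated synthetic diameter dataset for one technique
#'
#' Draws replicate-level mean offsets from a zero-mean normal with SD
#' `replicate_effect_sd_nm`, then within-replicate normal diameters around
#' the shifted mean with the calibrated SD. Non-positive draws are redrawn
#' (vanishingly rare at the shipped calibration). With `exact_moments`, the
#' pooled sample is affinely standardised so its mean and SD match the
#' calibration to machine precision.
#'
#' @param config A [generator_config()].
#' @param technique Technique label present in the calibration table.
#' @param seed Integer seed; defaults to the config seed.
#' @return A [diameter_dataset()].
#' @examples
#' d <- generate_technique_dataset(generator_config(), "cryo")
#' c(mean(d$diameter_nm), sd(d$diameter_nm))  # 138, 21
#' @export
generate_technique_dataset <- function(config, technique,
                                       seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  row <- .cal_row(config, technique)
  n_rep <- row$n_replicates
  n_per <- row$n_per_replicate
  x <- local_seed(seed, {
    offs <- stats::rnorm(n_rep, 0, row$replicate_effect_sd_nm)
    unlist(lapply(seq_len(n_rep), function(k) {
      v <- stats::rnorm(n_per, row$mean_nm + offs[k], row$sd_nm)
      while (any(v <= 0)) {
        v[v <= 0] <- stats::rnorm(sum(v <= 0), row$mean_nm + offs[k],
                                  row$sd_nm)
      }
      v
    }))
  })
  if (config$exact_moments && row$sd_nm > 0) {
    x <- (x - mean(x)) / stats::sd(x) * row$sd_nm + row$mean_nm
  } else if (config$exact_moments) {
    x <- rep(row$mean_nm, length(x))
  }
  if (any(x <= 0)) stop("standardisation produced non-positive diameters; ",
                        "calibration SD is too large relative to the mean")
  diameter_dataset(technique, rep(seq_len(n_rep), each = n_per), x)
}

#' Generate a UTS dataset by stereological sectioning
#'
#' Emulates ultra-thin-section TEM sizing mechanistically: true particle
#' diameters are drawn from the calibrated distribution of a reference
#' technique (default cryo-TEM, the least perturbed modality), each particle
#' is sectioned once at a random position under the model's scheme, and
#' sections below the model's detection limit are discarded (unidentifiable
#' during image analysis). The recorded apparent mean falls below the true
#' mean by the stereological factor, partially offset by the detection limit.
#'
#' @param config A [generator_config()].
#' @param model A [sectioning_model()]; its `scheme` and `detection_limit`
#'   are applied (its `D_actual` is ignored in favour of the drawn true
#'   sizes).
#' @param true_size_source Technique label whose calibration supplies the
#'   true-size distribution.
#' @param n_particles Number of particles to section.
#' @param seed Integer seed; defaults to the config seed.
#' @return A [diameter_dataset()] labelled `"uts"` with one replicate;
#'   typically shorter than `n_particles` when a detection limit applies.
#' @export
generate_uts_dataset_by_sectioning <- function(config, model,
                                               true_size_source = "cryo",
                                               n_particles = 10000L,
                                               seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            inherits(model, "sectioning_model"))
  row <- .cal_row(config, true_size_source)
  if (n_particles < 1) stop("`n_particles` must be >= 1")
  d <- local_seed(seed, {
    D <- stats::rnorm(n_particles, row$mean_nm, row$sd_nm)
    while (any(D <= 0)) {
      D[D <= 0] <- stats::rnorm(sum(D <= 0), row$mean_nm, row$sd_nm)
    }
    R <- D / 2
    u <- stats::runif(n_particles)
    r <- switch(model$scheme,
                volume_weighted = R * u^(1 / 3),
                uniform_plane   = R * u)
    D * sqrt(pmax(0, 1 - (2 * r / D)^2))
  })
  d <- d[d >= model$detection_limit & d > 0]
  if (length(d) == 0L) stop("no sections survived the detection limit")
  diameter_dataset("uts", 1L, d)
}

#' Simulate an NTA particle sample
#'
#' Nanoparticle tracking analysis sizes particles one track at a time, so a
#' small aggregate subpopulation inflates the sample mean while barely moving
#' the mode. Draws from a two-component lognormal mixture: the main
#' population parameterised by its mode and log-scale SD, and an aggregate
#' component parameterised by mean and SD, entered with probability
#' `nta_aggregate_fraction`.
#'
#' @param config A [generator_config()].
#' @param n_particles Number of tracked particles (>= 1).
#' @param seed Integer seed; defaults to the config seed.
#' @return Numeric vector of per-particle diameters, nm.
#' @seealso [sample_mode()] for the kernel-density mode estimate.
#' @export
simulate_nta_sample <- function(config, n_particles, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n_particles) || length(n_particles) != 1L || n_particles < 1) {
    stop("`n_particles` must be >= 1")
  }
  n_particles <- as.integer(n_particles)
  s <- config$nta_sigma
  mu_main <- log(config$nta_mode_nm) + s^2  # lognormal mode = exp(mu - s^2)
  cv2 <- (config$nta_aggregate_sd_nm / config$nta_aggregate_mean_nm)^2
  s_agg <- sqrt(log(1 + cv2))
  mu_agg <- log(config$nta_aggregate_mean_nm) - s_agg^2 / 2
  local_seed(seed, {
    agg <- stats::runif(n_particles) < config$nta_aggregate_fraction
    d <- numeric(n_particles)
    d[!agg] <- stats::rlnorm(sum(!agg), mu_main, s)
    d[agg] <- stats::rlnorm(sum(agg), mu_agg, s_agg)
    d
  })
}

#' Kernel-density mode of a sample
#'
#' The NTA report's "mode diameter": location of the maximum of a Gaussian
#' kernel density estimate of the sample.
#'
#' @param x Numeric sample.
#' @param ... Passed to [stats::density()].
#' @return Mode estimate (same units as `x`).
#' @export
sample_mode <- function(x, ...) {
  dens <- stats::density(x, ...)
  dens$x[which.max(dens$y)]
}
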