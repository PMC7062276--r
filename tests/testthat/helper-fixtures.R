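# shared fixtures: a tiny calibration for fast stochastic checks and the
# shipped full-size configuration
small_config <- function(...) {
  cal <- default_calibration()
  cal$n_per_replicate <- 30L
  generator_config(calibration = cal, ...)
}

default_config <- function(...) generator_config(...)

# unit cube centred at the origin, as a convex particle
unit_cube <- function() {
  convex_particle(as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5),
                                        c(-0.5, 0.5))))
}
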