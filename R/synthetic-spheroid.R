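#' Synthetic spheroid compaction track under osmotic pressure
#'
#' Generates a spheroid geometry time course under a known osmotic pressure:
#' after t = 0 the effective diameter sits at the linear-elastic equilibrium
#' `d0 * (1 - eps)` with `eps = p (1 - 2 nu) / E`, plus additive Gaussian
#' measurement noise on the diameter. Projected areas are consistent with
#' the diameters assuming circular projection. The t = 0 measurement is the
#' noise-free reference. Defaults emulate the compression assay: a ~450 um
#' spheroid imaged at t = 0, 3, 6, 24, 30 and 48 h.
#'
#' @param d0 Initial effective diameter (um, > 0).
#' @param pressure Applied osmotic pressure (Pa, >= 0).
#' @param body A [gel_calibration()] describing the elastic response.
#' @param times Measurement times in hours (first must be 0).
#' @param noise_sd Diameter measurement noise SD (um).
#' @param seed Integer RNG seed.
#' @return A [spheroid_track()].
#' @export
make_spheroid_track <- function(d0 = 450, pressure = 2000,
                                body = gel_calibration(),
                                times = c(0, 3, 6, 24, 30, 48),
                                noise_sd = 1, seed = 1L) {
  if (d0 <= 0) stop("`d0` must be positive")
  if (pressure < 0) stop("`pressure` must be >= 0")
  set.seed(seed)
  eps <- strain_from_pressure(pressure, body$youngs_modulus,
                              body$poisson_ratio)
  d <- rep(d0 * (1 - eps), length(times))
  d[1] <- d0
  if (noise_sd > 0 && length(times) > 1L)
    d[-1] <- d[-1] + stats::rnorm(length(times) - 1L, 0, noise_sd)
  spheroid_track(times, diameter = d)
}
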