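#' Calibration gel for osmotic-compression experiments
#'
#' Mechanical description of the polyacrylamide calibration disc (and, by
#' extension, of any linearly elastic body compressed osmotically). Young's
#' modulus is derived from the shear modulus measured by rheometry through
#' the isotropic identity `E = 2 G (1 + nu)`. Defaults: G = 5150 Pa (shear
#' rheometry of the calibration gel), nu = 0.457.
#'
#' @param shear_modulus Shear modulus G in Pa (> 0).
#' @param poisson_ratio Poisson ratio nu in \[0, 0.5).
#' @param pre_diameter,post_diameter Optional measured disc diameters (um)
#'   before/after dextran addition.
#' @return Object of class `gel_calibration` with derived `youngs_modulus`.
#' @export
gel_calibration <- function(shear_modulus = 5150, poisson_ratio = 0.457,
                            pre_diameter = NA_real_,
                            post_diameter = NA_real_) {
  E <- modulus_from_shear(shear_modulus, poisson_ratio)
  structure(list(shear_modulus = shear_modulus,
                 poisson_ratio = poisson_ratio,
                 youngs_modulus = E,
                 pre_diameter = pre_diameter,
                 post_diameter = post_diameter),
            class = "gel_calibration")
}

#' Young's modulus from shear modulus
#'
#' Standard isotropic linear-elastic identity `E = 2 G (1 + nu)`, linking the
#' rheometry measurement to the elastic compression model.
#'
#' @param G Shear modulus in Pa (> 0).
#' @param nu Poisson ratio in \[0, 0.5).
#' @return Young's modulus in Pa.
#' @export
modulus_from_shear <- function(G, nu) {
  if (G <= 0) stop("`G` must be positive")
  if (nu < 0 || nu >= 0.5) stop("`nu` must be in [0, 0.5)")
  2 * G * (1 + nu)
}

#' Effective diameter from a projected area
#'
#' Assuming a spherical structure, the effective diameter of a spheroid with
#' projected area `A` is `d = 2 sqrt(A / pi)`.
#'
#' @param area Projected area in um^2 (>= 0).
#' @return Effective diameter in um.
#' @export
effective_diameter <- function(area) {
  if (any(area < 0)) stop("`area` must be >= 0")
  2 * sqrt(area / pi)
}

#' Spheroid geometry track
#'
#' Projected area / effective diameter of one spheroid over time. Supply
#' either areas or diameters; the other is filled in assuming circular
#' projection. The first timepoint must be t = 0 (the pre-compression
#' reference).
#'
#' @param times Times in hours, starting at 0, strictly increasing.
#' @param area Projected areas in um^2.
#' @param diameter Effective diameters in um.
#' @return Data frame of class `spheroid_track` with columns
#'   `time_h, area_um2, diameter_um`.
#' @export
spheroid_track <- function(times, area = NULL, diameter = NULL) {
  if (times[1] != 0) stop("track must start at t = 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(diameter)) {
    if (is.null(area)) stop("supply `area` or `diameter`")
    diameter <- effective_diameter(area)
  }
  if (is.null(area)) area <- pi * (diameter / 2)^2
  if (any(diameter <= 0)) stop("diameters must be positive")
  out <- data.frame(time_h = times, area_um2 = area, diameter_um = diameter)
  class(out) <- c("spheroid_track", "data.frame")
  out
}

#' Compressive strain time course of a spheroid
#'
#' Diameter-based engineering strain relative to the t = 0 reference,
#' `eps(t) = (d(0) - d(t)) / d(0)`, reported positive in compression.
#'
#' @param track A [spheroid_track()].
#' @return Numeric vector of strains, one per timepoint (`eps(0) = 0`).
#' @export
strain_timeseries <- function(track) {
  if (track$time_h[1] != 0) stop("track must include t = 0")
  d0 <- track$diameter_um[1]
  if (d0 <= 0) stop("reference diameter must be positive")
  (d0 - track$diameter_um) / d0
}

#' Pressure from compressive strain (linear-elastic closed form)
#'
#' For a homogeneous isotropic linear-elastic body under uniform pressure `p`
#' on its free surfaces with a frictionless support, the stress state is
#' uniform hydrostatic (`sigma = -p I`) and every linear dimension contracts
#' by the strain `eps = p (1 - 2 nu) / E`. This closed form is the exact
#' solution of the axisymmetric boundary-value problem (pressure on top and
#' side, roller on the bottom) that a finite-element solve would only
#' approximate, so the inversion is performed directly:
#' `p = eps E / (1 - 2 nu)`.
#'
#' @param eps Diameter-based compressive strain, in \[0, 1).
#' @param E Young's modulus in Pa.
#' @param nu Poisson ratio, < 0.5 (at nu = 0.5 the material is incompressible
#'   and pressure cannot be inferred from strain).
#' @return Pressure in Pa.
#' @export
pressure_from_strain <- function(eps, E, nu) {
  if (nu >= 0.5) stop("pressure is indeterminate at nu >= 0.5 (incompressible)")
  if (any(eps < 0) || any(eps >= 1)) stop("`eps` must be in [0, 1)")
  eps * E / (1 - 2 * nu)
}

#' @rdname pressure_from_strain
#' @param p Pressure in Pa (>= 0).
#' @return For `strain_from_pressure()`: the compressive strain
#'   `eps = p (1 - 2 nu) / E`.
#' @export
strain_from_pressure <- function(p, E, nu) {
  if (any(p < 0)) stop("`p` must be >= 0")
  if (nu >= 0.5) stop("`nu` must be < 0.5")
  p * (1 - 2 * nu) / E
}

#' Recover the applied pressure from a spheroid track
#'
#' Inverts the equilibrium compressive strain (mean over all t > 0
#' timepoints) through [pressure_from_strain()].
#'
#' @param track A [spheroid_track()] (or list of tracks, pooled).
#' @param gel A [gel_calibration()] providing E and nu.
#' @return Pressure in Pa.
#' @export
recover_pressure <- function(track, gel = gel_calibration()) {
  if (inherits(track, "spheroid_track")) track <- list(track)
  eps <- unlist(lapply(track, function(tr) {
    e <- strain_timeseries(tr)
    e[tr$time_h > 0]
  }))
  if (length(eps) == 0L) stop("no post-reference timepoints in track")
  pressure_from_strain(max(mean(eps), 0), gel$youngs_modulus,
                       gel$poisson_ratio)
}

#' Calibrate the osmotic load of a dextran concentration
#'
#' Converts measured pre-/post-compression calibration-disc diameters into
#' the applied osmotic pressure via the linear-elastic closed form, tagging
#' the result with the dextran concentration. Apparent swelling
#' (`post > pre`) yields a zero pressure with a warning.
#'
#' @param pre_d,post_d Disc diameters (um) before and after dextran addition.
#' @param gel A [gel_calibration()].
#' @param concentration Dextran concentration in mg/mL.
#' @return Object of class `osmotic_load`: `concentration_mg_ml`,
#'   `pressure_pa`, `strain`.
#' @export
calibrate_osmotic_load <- function(pre_d, post_d, gel = gel_calibration(),
                                   concentration = NA_real_) {
  if (pre_d <= 0) stop("`pre_d` must be positive")
  if (post_d > pre_d) {
    warning("post-compression diameter exceeds pre-compression; reporting p = 0")
    eps <- 0
  } else {
    eps <- (pre_d - post_d) / pre_d
  }
  p <- pressure_from_strain(eps, gel$youngs_modulus, gel$poisson_ratio)
  structure(list(concentration_mg_ml = concentration, pressure_pa = p,
                 strain = eps),
            class = "osmotic_load")
}

#' Read / write spheroid tracks as CSV
#'
#' Track CSV has columns `time_h` and `area_um2` (or `diameter_um`).
#'
#' @param path CSV path.
#' @return A [spheroid_track()].
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- utils::read.csv(path)
  if ("diameter_um" %in% names(df))
    spheroid_track(df$time_h, diameter = df$diameter_um)
  else if ("area_um2" %in% names(df))
    spheroid_track(df$time_h, area = df$area_um2)
  else stop("track CSV needs a time_h plus area_um2 or diameter_um column")
}

#' @rdname read_track_csv
#' @param track A [spheroid_track()].
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
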