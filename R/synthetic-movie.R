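#' Contractile-patch scenario for synthetic traction movies
#'
#' Describes one or more "contractile patches": circular regions whose rim
#' pulls inward, emulating the compressive radial stress pattern measured
#' around fusing syncytial patches. Tractions are zero before `onset_time`,
#' ramp linearly over 2 h after onset, then stay constant (matching the
#' observed ~6-12 h transition to a plateau without inventing dynamics).
#'
#' @param patch_center Patch center(s) in um: length-2 vector or an n x 2
#'   matrix (x, y) for multiple patches.
#' @param patch_radius Patch radius (um), recycled across patches, > 0.
#' @param peak_traction Plateau traction magnitude at the patch rim (Pa),
#'   recycled, >= 0. Absolute magnitudes are set to order 10-100 Pa, typical
#'   for soft-gel traction microscopy.
#' @param onset_time Contraction onset in hours.
#' @param field_extent Image size in px (`c(ny, nx)` or scalar).
#' @param pixel_size Pixel size in um.
#' @param ring_width Gaussian width of the rim traction annulus (um);
#'   defaults to a third of the patch radius.
#' @param seed Integer RNG seed.
#' @return Object of class `contraction_scenario`.
#' @export
contraction_scenario <- function(patch_center, patch_radius = 25,
                                 peak_traction = 40, onset_time = 6,
                                 field_extent = c(512L, 512L),
                                 pixel_size = 0.3086,
                                 ring_width = NULL, seed = 1L) {
  if (is.null(dim(patch_center)))
    patch_center <- matrix(patch_center, ncol = 2)
  n <- nrow(patch_center)
  patch_radius <- rep_len(patch_radius, n)
  peak_traction <- rep_len(peak_traction, n)
  if (any(patch_radius <= 0)) stop("`patch_radius` must be positive")
  if (any(peak_traction < 0)) stop("`peak_traction` must be >= 0")
  if (length(field_extent) == 1L) field_extent <- rep(field_extent, 2L)
  field_extent <- as.integer(field_extent)
  if (is.null(ring_width)) ring_width <- patch_radius / 3
  ring_width <- rep_len(ring_width, n)
  ext_um <- rev(field_extent) * pixel_size # (x, y) extent
  reach <- patch_radius + 3 * ring_width
  if (any(patch_center[, 1] - reach < 0) || any(patch_center[, 1] + reach > ext_um[1]) ||
      any(patch_center[, 2] - reach < 0) || any(patch_center[, 2] + reach > ext_um[2]))
    stop("patch (rim annulus included) must lie fully inside the field extent")
  structure(list(patch_center = patch_center, patch_radius = patch_radius,
                 peak_traction = peak_traction, onset_time = onset_time,
                 field_extent = field_extent, pixel_size = pixel_size,
                 ring_width = ring_width, seed = as.integer(seed)),
            class = "contraction_scenario")
}

# Traction ramp: 0 before onset, linear over 2 h, then plateau at 1.
ramp_factor <- function(t, onset, ramp_h = 2) {
  pmin(pmax((t - onset) / ramp_h, 0), 1)
}

# Analytic plateau traction (Pa) at positions (x_um, y_um): sum over patches
# of an inward-pointing Gaussian rim annulus.
scenario_traction <- function(scenario, x_um, y_um) {
  tx <- numeric(length(x_um)); ty <- numeric(length(x_um))
  for (j in seq_len(nrow(scenario$patch_center))) {
    dx <- x_um - scenario$patch_center[j, 1]
    dy <- y_um - scenario$patch_center[j, 2]
    rho <- sqrt(dx^2 + dy^2)
    mag <- scenario$peak_traction[j] *
      exp(-(rho - scenario$patch_radius[j])^2 / (2 * scenario$ring_width[j]^2))
    ok <- rho > 1e-9
    tx[ok] <- tx[ok] - mag[ok] * dx[ok] / rho[ok]
    ty[ok] <- ty[ok] - mag[ok] * dy[ok] / rho[ok]
  }
  cbind(tx, ty)
}

#' Synthetic contraction movie with ground-truth tractions
#'
#' Generates a time-lapse bead image stack (one frame per requested time)
#' for a contractile-patch scenario on an elastic substrate, together with
#' the ground-truth traction field per time sampled on the PIV output
#' lattice. Displacements are computed by the forward Boussinesq solver on a
#' fine generator lattice and interpolated at bead positions; frames are
#' rendered by moving bead centers (forward warping). Traction is zero
#' before `onset_time`, so early frames equal the reference frame up to
#' noise; a frame whose displacement is exactly zero reuses frame 1
#' verbatim.
#'
#' @param scenario A [contraction_scenario()].
#' @param substrate An [elastic_substrate()].
#' @param times Acquisition times in hours, starting at 0 (e.g. every 0.5 h
#'   over 48 h).
#' @param bead_spec A [bead_image_spec()]; defaults to the scenario extent.
#' @param cfg A [piv_config()] defining the ground-truth lattice.
#' @param gen_spacing Generator lattice spacing in px for the forward solve.
#' @return List with `stack` (list of frames), `times`, `truth` (list of
#'   [traction_field()]s), `scenario`, `bead_spec`.
#' @export
make_contraction_movie <- function(scenario, substrate = elastic_substrate(),
                                   times = seq(0, 48, by = 0.5),
                                   bead_spec = NULL,
                                   cfg = piv_config(pixel_size = substrate$pixel_size),
                                   gen_spacing = 6L) {
  if (times[1] != 0) stop("times must start at 0 (the reference frame)")
  if (is.null(bead_spec))
    bead_spec <- bead_image_spec(image_size = scenario$field_extent,
                                 pixel_size = scenario$pixel_size,
                                 seed = scenario$seed)
  px <- scenario$pixel_size
  dim_img <- scenario$field_extent
  # plateau traction on the generator lattice -> plateau displacement (um)
  gen_x <- seq(1, dim_img[2], by = gen_spacing)
  gen_y <- seq(1, dim_img[1], by = gen_spacing)
  gg <- expand.grid(y = gen_y, x = gen_x)
  tv <- scenario_traction(scenario, gg$x * px, gg$y * px)
  t_base <- traction_field(gen_x, gen_y,
                           matrix(tv[, 1], length(gen_y), length(gen_x)),
                           matrix(tv[, 2], length(gen_y), length(gen_x)),
                           pixel_size = px)
  u_base <- forward_displacement(t_base, substrate)
  set.seed(bead_spec$seed)
  pos <- draw_bead_positions(bead_spec)
  ub_px <- bilin_at(gen_x, gen_y, u_base$u, pos[, 1], pos[, 2]) / px
  vb_px <- bilin_at(gen_x, gen_y, u_base$v, pos[, 1], pos[, 2]) / px
  lim <- min(cfg$window_sizes) / 4
  if (max(sqrt(ub_px^2 + vb_px^2)) >= lim)
    stop(sprintf(
      "peak displacement %.2f px exceeds a quarter of the smallest window; reduce peak_traction",
      max(sqrt(ub_px^2 + vb_px^2))))
  g <- piv_grid(dim_img, min(cfg$window_sizes),
                if (cfg$final_spacing_rule == "half-window")
                  min(cfg$window_sizes) %/% 2L else min(cfg$window_sizes))
  lat <- expand.grid(y = g$cy, x = g$cx)
  t_lat <- scenario_traction(scenario, lat$x * px, lat$y * px)
  nyv <- length(g$cy); nxv <- length(g$cx)
  stack <- vector("list", length(times))
  truth <- vector("list", length(times))
  base_img <- render_beads(pos, dim_img, bead_spec$bead_sigma)
  zero_disp <- all(ub_px == 0) && all(vb_px == 0)
  for (i in seq_along(times)) {
    m <- ramp_factor(times[i], scenario$onset_time)
    still <- m == 0 || zero_disp
    if (still && i > 1L) {
      # no motion since the reference: reuse frame 1 verbatim
      stack[[i]] <- stack[[1]]
    } else {
      frame <- if (still) base_img else
        render_beads(pos + m * cbind(ub_px, vb_px), dim_img,
                     bead_spec$bead_sigma)
      if (bead_spec$noise_sd > 0) {
        set.seed(bead_spec$seed + 1000L + i)
        frame <- frame + matrix(stats::rnorm(length(frame), 0, bead_spec$noise_sd),
                                nrow(frame), ncol(frame))
      }
      stack[[i]] <- frame
    }
    truth[[i]] <- traction_field(g$cx, g$cy,
                                 matrix(m * t_lat[, 1], nyv, nxv),
                                 matrix(m * t_lat[, 2], nyv, nxv),
                                 pixel_size = px, time = times[i])
  }
  list(stack = stack, times = times, truth = truth,
       scenario = scenario, bead_spec = bead_spec)
}
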