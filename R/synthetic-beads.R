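#' Specification for synthetic fluorescent-bead images
#'
#' Parameters of the bead-image renderer used to exercise the PIV stage with
#' known ground truth. Beads are rendered as isotropic Gaussian spots (the
#' simplest point-spread model sufficient for cross-correlation PIV) with
#' additive Gaussian read noise. Defaults emulate imaging of 0.5-um
#' fluorescent beads at 0.3086 um/px: spot sigma 1.5 px and a bead density
#' high enough to give 10-20 beads per final 48-px interrogation window.
#'
#' @param image_size Image size in px, `c(ny, nx)` or a scalar for square.
#' @param bead_density Beads per um^2 (> 0).
#' @param bead_sigma Gaussian spot sigma in px.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the unit bead
#'   peak amplitude (>= 0).
#' @param pixel_size Pixel size in um.
#' @param seed Integer RNG seed; all rendering is deterministic given it.
#' @return Object of class `bead_image_spec`.
#' @export
bead_image_spec <- function(image_size = c(512L, 512L), bead_density = 0.08,
                            bead_sigma = 1.5, noise_sd = 0.02,
                            pixel_size = 0.3086, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (bead_density <= 0) stop("`bead_density` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (bead_sigma <= 0) stop("`bead_sigma` must be positive")
  structure(list(image_size = image_size, bead_density = bead_density,
                 bead_sigma = bead_sigma, noise_sd = noise_sd,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "bead_image_spec")
}

# Render Gaussian bead spots at subpixel positions (pos: n x 2 matrix of
# (x, y) px). Beads slightly outside the frame still contribute their tails.
render_beads <- function(pos, dim_img, sigma) {
  ny <- dim_img[1]; nx <- dim_img[2]
  img <- matrix(0, ny, nx)
  r <- ceiling(4 * sigma)
  for (b in seq_len(nrow(pos))) {
    x <- pos[b, 1]; y <- pos[b, 2]
    xs <- (floor(x) - r):(floor(x) + r)
    ys <- (floor(y) - r):(floor(y) + r)
    kx <- xs >= 1L & xs <= nx
    ky <- ys >= 1L & ys <= ny
    if (!any(kx) || !any(ky)) next
    gx <- exp(-((xs[kx] - x)^2) / (2 * sigma^2))
    gy <- exp(-((ys[ky] - y)^2) / (2 * sigma^2))
    img[ys[ky], xs[kx]] <- img[ys[ky], xs[kx]] + outer(gy, gx)
  }
  img
}

# Draw bead positions for a spec; margin lets beads sit just outside the
# frame so border windows stay populated after deformation.
draw_bead_positions <- function(spec, margin = 8) {
  area_um2 <- prod(spec$image_size) * spec$pixel_size^2
  n <- max(1L, round(spec$bead_density * area_um2))
  cbind(x = stats::runif(n, 1 - margin, spec$image_size[2] + margin),
        y = stats::runif(n, 1 - margin, spec$image_size[1] + margin))
}

# Evaluate a displacement function field(x, y) -> (u, v) in px; accepts a
# list(u, v) or two-column return.
eval_field <- function(field, x, y) {
  res <- field(x, y)
  if (is.list(res)) cbind(res$u, res$v) else res
}

#' Synthetic bead image pair with known displacement field
#'
#' Renders a reference bead image and a deformed copy in which every bead is
#' translated by a user-supplied continuous displacement function (forward
#' warping of bead centers, so the ground truth carries no interpolation
#' bias). The analytic field sampled on the PIV output lattice is returned as
#' ground truth. Frames receive independent additive noise, except that a
#' field which is exactly zero everywhere returns the reference frame
#' verbatim (the deformed image is then bit-identical by construction).
#'
#' @param spec A [bead_image_spec()].
#' @param field Function `(x_px, y_px) -> displacement (u, v) in px`
#'   (list or two-column matrix).
#' @param cfg A [piv_config()]; defines the ground-truth lattice and the
#'   displacement-magnitude precondition (max |d| must stay below a quarter
#'   of the smallest interrogation window).
#' @return List with `reference`, `deformed` (matrices) and `truth`
#'   (a [displacement_field()] in um on the final PIV lattice).
#' @export
make_bead_pair <- function(spec, field, cfg = piv_config(pixel_size = spec$pixel_size)) {
  set.seed(spec$seed)
  pos <- draw_bead_positions(spec)
  disp <- eval_field(field, pos[, 1], pos[, 2])
  g <- piv_grid(spec$image_size, min(cfg$window_sizes),
                if (cfg$final_spacing_rule == "half-window")
                  min(cfg$window_sizes) %/% 2L else min(cfg$window_sizes))
  gxy <- expand.grid(y = g$cy, x = g$cx)
  gt <- eval_field(field, gxy$x, gxy$y)
  lim <- min(cfg$window_sizes) / 4
  mx <- max(sqrt(disp[, 1]^2 + disp[, 2]^2), sqrt(gt[, 1]^2 + gt[, 2]^2))
  if (mx >= lim)
    stop(sprintf(
      "displacement magnitude %.2f px exceeds a quarter of the smallest window (%.2f px)",
      mx, lim))
  ref <- render_beads(pos, spec$image_size, spec$bead_sigma)
  if (spec$noise_sd > 0)
    ref <- ref + matrix(stats::rnorm(length(ref), 0, spec$noise_sd),
                        nrow(ref), ncol(ref))
  if (all(disp == 0)) {
    def <- ref
  } else {
    def <- render_beads(pos + disp, spec$image_size, spec$bead_sigma)
    if (spec$noise_sd > 0)
      def <- def + matrix(stats::rnorm(length(def), 0, spec$noise_sd),
                          nrow(def), ncol(def))
  }
  nyv <- length(g$cy); nxv <- length(g$cx)
  truth <- displacement_field(
    x = g$cx, y = g$cy,
    u = matrix(gt[, 1], nyv, nxv) * spec$pixel_size,
    v = matrix(gt[, 2], nyv, nxv) * spec$pixel_size,
    pixel_size = spec$pixel_size)
  list(reference = ref, deformed = def, truth = truth)
}
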