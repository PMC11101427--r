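#' Elastic substrate description
#'
#' Linear-elastic half-space parameters of the traction force microscopy
#' substrate. Defaults are the polyacrylamide gel used for the trophoblast
#' monolayer experiments: Young's modulus 3900 Pa, Poisson ratio 0.457,
#' camera pixel 0.3086 um.
#'
#' @param youngs_modulus Young's modulus in Pa (> 0).
#' @param poisson_ratio Poisson ratio, in \[0, 0.5).
#' @param pixel_size Pixel size in um.
#' @return Object of class `elastic_substrate`.
#' @export
elastic_substrate <- function(youngs_modulus = 3900,
                              poisson_ratio = 0.457,
                              pixel_size = 0.3086) {
  if (youngs_modulus <= 0) stop("`youngs_modulus` must be positive")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must be in [0, 0.5)")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 pixel_size = pixel_size),
            class = "elastic_substrate")
}

#' FTTC configuration
#'
#' Inversion settings for Fourier-transform traction cytometry.
#'
#' `lambda` is a dimensionless 0th-order Tikhonov factor expressed relative to
#' the squared kernel gain at the highest resolved wavevector: the absolute
#' regularizer is `lambda * g_max^2` where `g_max` is the Boussinesq kernel
#' gain at the lattice Nyquist wavevector. The default 99 damps the
#' highest-wavevector response ~100-fold while leaving long-wavelength modes
#' (whose gain is far larger) essentially untouched.
#'
#' @param lambda Dimensionless Tikhonov factor, >= 0.
#' @param zero_pad_factor Integer >= 1; the field is zero-padded to this
#'   multiple of its extent before the FFT to suppress periodic wrap-around.
#' @return Object of class `fttc_config`.
#' @export
fttc_config <- function(lambda = 99, zero_pad_factor = 2L) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  zero_pad_factor <- as.integer(zero_pad_factor)
  if (zero_pad_factor < 1L) stop("`zero_pad_factor` must be >= 1")
  structure(list(lambda = lambda, zero_pad_factor = zero_pad_factor),
            class = "fttc_config")
}

#' Gridded traction field
#'
#' Traction stress vectors (Pa) on the same regular lattice as the source
#' displacement field. Stresses are relative to the reference (t = 0)
#' configuration.
#'
#' @param x,y Lattice coordinates (px).
#' @param tx,ty Traction components (Pa), matrices `length(y) x length(x)`.
#' @param pixel_size Pixel size (um).
#' @param time Time in hours.
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(x, y, tx, ty, pixel_size = 0.3086,
                           time = NA_real_) {
  dm <- c(length(y), length(x))
  if (!all(dim(tx) == dm) || !all(dim(ty) == dm))
    stop("tx/ty dimensions must be length(y) x length(x)")
  if (any(!is.finite(tx)) || any(!is.finite(ty)))
    stop("traction values must be finite")
  structure(
    list(x = x, y = y, tx = tx, ty = ty, pixel_size = pixel_size,
         spacing_px = if (length(x) > 1L) diff(x)[1] else NA_real_,
         spacing_um = if (length(x) > 1L) diff(x)[1] * pixel_size else NA_real_,
         time = time),
    class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf(
    "<traction_field> %d x %d vectors, spacing %.2f um, t = %s h, |T| max %.2f Pa\n",
    length(x$y), length(x$x), x$spacing_um, format(x$time),
    max(sqrt(x$tx^2 + x$ty^2))))
  invisible(x)
}

#' @describeIn traction_field Long-format data frame
#'   (`x_px, y_px, t_x_Pa, t_y_Pa, time_h`).
#' @param row.names,optional,... Compatibility arguments; unused.
#' @export
as.data.frame.traction_field <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  g <- expand.grid(y_px = x$y, x_px = x$x)
  data.frame(x_px = g$x_px, y_px = g$y_px,
             t_x_Pa = as.vector(x$tx), t_y_Pa = as.vector(x$ty),
             time_h = x$time)
}

# Boussinesq half-space kernel in Fourier space on an ny x nx lattice with
# spacing h (um). Returns the 2x2 symmetric tensor components (um/Pa) with the
# DC entry zeroed, plus the reference gain at the Nyquist wavevector.
fttc_kernel <- function(ny, nx, h, E, nu) {
  kx <- 2 * pi * fftfreq(nx, h)
  ky <- 2 * pi * fftfreq(ny, h)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  k2 <- KX^2 + KY^2
  k <- sqrt(k2)
  k[1, 1] <- Inf # silence DC division; entries are zeroed below
  A <- 2 * (1 + nu) / E
  Gxx <- A * ((1 - nu) * k2 + nu * KY^2) / k^3
  Gyy <- A * ((1 - nu) * k2 + nu * KX^2) / k^3
  Gxy <- -A * nu * KX * KY / k^3
  Gxx[1, 1] <- 0; Gyy[1, 1] <- 0; Gxy[1, 1] <- 0
  # The off-diagonal term is odd in kx and ky; at the Nyquist bin of an even
  # lattice the sign of the wavevector is ambiguous, so a real symmetric
  # convolution operator requires Gxy = 0 there.
  if (nx %% 2L == 0L) Gxy[, nx / 2L + 1L] <- 0
  if (ny %% 2L == 0L) Gxy[ny / 2L + 1L, ] <- 0
  kmax <- sqrt(max(k2))
  list(Gxx = Gxx, Gxy = Gxy, Gyy = Gyy,
       g_ref = A * (1 - nu) / kmax)
}

# Shared padded-FFT machinery: embeds the two field components in a
# zero-padded array, applies `fun` to their transforms, crops back.
fttc_apply <- function(fx, fy, h, pad, fun) {
  ny <- nrow(fx); nx <- ncol(fx)
  nyp <- pad * ny; nxp <- pad * nx
  PX <- matrix(0, nyp, nxp); PY <- matrix(0, nyp, nxp)
  PX[1:ny, 1:nx] <- fx; PY[1:ny, 1:nx] <- fy
  FX <- stats::fft(PX); FY <- stats::fft(PY)
  out <- fun(FX, FY, nyp, nxp)
  list(x = ifft_re(out[[1]])[1:ny, 1:nx],
       y = ifft_re(out[[2]])[1:ny, 1:nx])
}

#' Forward Boussinesq solution: tractions to displacements
#'
#' Computes the surface displacement field generated by a traction field on a
#' linear-elastic half-space, via the Fourier-space Boussinesq tensor
#' `u~(k) = G~(k) T~(k)`. The DC (net-force) mode is set to zero, consistent
#' with force balance over the field of view.
#'
#' @param traction A [traction_field()] on a regular lattice.
#' @param substrate An [elastic_substrate()].
#' @param cfg An [fttc_config()] (only the padding factor is used).
#' @return A [displacement_field()] on the same lattice (um).
#' @export
forward_displacement <- function(traction, substrate, cfg = fttc_config()) {
  if (length(traction$x) > 1L) {
    sp <- diff(traction$x)
    if (max(abs(sp - sp[1])) > 1e-6) stop("traction lattice must be regular")
  }
  h <- traction$spacing_um
  res <- fttc_apply(traction$tx, traction$ty, h, cfg$zero_pad_factor,
    function(FX, FY, nyp, nxp) {
      K <- fttc_kernel(nyp, nxp, h, substrate$youngs_modulus,
                       substrate$poisson_ratio)
      list(K$Gxx * FX + K$Gxy * FY, K$Gxy * FX + K$Gyy * FY)
    })
  displacement_field(traction$x, traction$y, res$x, res$y,
                     pixel_size = substrate$pixel_size, time = traction$time)
}

#' Invert displacements to tractions (FTTC)
#'
#' Regularized Fourier-transform traction cytometry: solves
#' `T~(k) = (G~' G~ + lambda I)^-1 G~' u~(k)` per wavevector with the
#' half-space Boussinesq tensor and 0th-order Tikhonov regularization, then
#' transforms back. The DC mode is zeroed, so the lattice sum of the
#' recovered tractions vanishes.
#'
#' @param displacement A [displacement_field()] with invalid vectors already
#'   filled (see [validate_and_fill()]).
#' @param substrate An [elastic_substrate()].
#' @param cfg An [fttc_config()].
#' @return A [traction_field()] in Pa on the same lattice.
#' @export
invert_traction <- function(displacement, substrate, cfg = fttc_config()) {
  if (length(displacement$x) > 1L) {
    sp <- diff(displacement$x)
    if (max(abs(sp - sp[1])) > 1e-6) stop("displacement lattice must be regular")
  }
  if (cfg$lambda == 0)
    warning("lambda = 0: unregularized inversion amplifies high-wavevector noise")
  h <- displacement$spacing_um
  res <- fttc_apply(displacement$u, displacement$v, h, cfg$zero_pad_factor,
    function(FX, FY, nyp, nxp) {
      K <- fttc_kernel(nyp, nxp, h, substrate$youngs_modulus,
                       substrate$poisson_ratio)
      lam <- cfg$lambda * K$g_ref^2
      M11 <- K$Gxx^2 + K$Gxy^2 + lam
      M22 <- K$Gyy^2 + K$Gxy^2 + lam
      M12 <- K$Gxy * (K$Gxx + K$Gyy)
      det <- M11 * M22 - M12^2
      det[det == 0] <- 1 # DC (and only DC) when lambda = 0; zeroed below
      Gu1 <- K$Gxx * FX + K$Gxy * FY
      Gu2 <- K$Gxy * FX + K$Gyy * FY
      T1 <- (M22 * Gu1 - M12 * Gu2) / det
      T2 <- (-M12 * Gu1 + M11 * Gu2) / det
      T1[1, 1] <- 0; T2[1, 1] <- 0
      list(T1, T2)
    })
  traction_field(displacement$x, displacement$y, res$x, res$y,
                 pixel_size = substrate$pixel_size, time = displacement$time)
}

#' Invert a displacement time series
#'
#' Applies [invert_traction()] to each field of a time-lapse series (e.g.
#' one field per 30-min interval over 48 h), preserving time order. Fields
#' must share one lattice; gaps in the time vector are recorded in the
#' `gaps` attribute, never interpolated.
#'
#' @param fields List of [displacement_field()]s with `time` set.
#' @param substrate An [elastic_substrate()].
#' @param cfg An [fttc_config()].
#' @return List of [traction_field()]s ordered by time.
#' @export
traction_timeseries <- function(fields, substrate, cfg = fttc_config()) {
  times <- vapply(fields, function(f) f$time, numeric(1))
  ord <- order(times)
  fields <- fields[ord]; times <- times[ord]
  x0 <- fields[[1]]$x; y0 <- fields[[1]]$y
  for (f in fields)
    if (!identical(f$x, x0) || !identical(f$y, y0))
      stop("all fields must share one lattice")
  out <- lapply(fields, invert_traction, substrate = substrate, cfg = cfg)
  if (length(times) > 2L) {
    dt <- diff(times)
    gap_at <- which(dt > 1.5 * stats::median(dt))
    attr(out, "gaps") <- times[gap_at]
  }
  out
}
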