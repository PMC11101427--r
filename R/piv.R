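#' PIV configuration
#'
#' Parameters of the iterative multi-pass particle image velocimetry step used
#' to recover bead displacements from image pairs. The defaults reproduce the
#' analysis settings of the trophoblast traction experiments: interrogation
#' windows shrinking over passes from 128 to 64 to 48 px, a correlation
#' acceptance threshold of 0.6, a camera pixel of 0.3086 um, and a final
#' lattice spacing of one (non-overlapping) final window, i.e. 48 px ~ 14.8 um.
#'
#' @param window_sizes Integer vector of interrogation window sizes in px,
#'   strictly decreasing, one per pass.
#' @param correlation_threshold Vectors whose correlation peak falls below this
#'   value are flagged invalid by [validate_and_fill()]. Must be in (0, 1).
#' @param pixel_size Physical pixel size in um.
#' @param final_spacing_rule Output lattice spacing on the last pass:
#'   `"window"` (spacing = final window size) or `"half-window"` (50% overlap).
#' @return An object of class `piv_config`.
#' @seealso [iterative_piv()], [validate_and_fill()]
#' @export
piv_config <- function(window_sizes = c(128L, 64L, 48L),
                       correlation_threshold = 0.6,
                       pixel_size = 0.3086,
                       final_spacing_rule = c("window", "half-window")) {
  final_spacing_rule <- match.arg(final_spacing_rule)
  window_sizes <- as.integer(window_sizes)
  if (length(window_sizes) < 1L || any(diff(window_sizes) >= 0))
    stop("`window_sizes` must be a strictly decreasing vector")
  if (any(window_sizes < 8L)) stop("windows below 8 px are not supported")
  if (correlation_threshold <= 0 || correlation_threshold >= 1)
    stop("`correlation_threshold` must be in (0, 1)")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(
    list(window_sizes = window_sizes,
         correlation_threshold = correlation_threshold,
         pixel_size = pixel_size,
         final_spacing_rule = final_spacing_rule),
    class = "piv_config")
}

#' Gridded displacement field
#'
#' Container for a bead displacement field on a regular lattice. Coordinates
#' are in the image frame (origin top-left, x along columns, y along rows,
#' y increasing downward), positions in px, displacements in um.
#'
#' @param x,y Lattice coordinates (px), ascending, uniformly spaced.
#' @param u,v Displacement components (um), matrices of dim
#'   `c(length(y), length(x))`.
#' @param corr Correlation coefficient per vector, in \[-1, 1\].
#' @param valid Logical matrix flagging usable vectors.
#' @param pixel_size Pixel size (um) used for the px/um conversion.
#' @param time Acquisition time in hours (optional).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(x, y, u, v, corr = NULL, valid = NULL,
                               pixel_size = 0.3086, time = NA_real_) {
  dm <- c(length(y), length(x))
  if (!all(dim(u) == dm) || !all(dim(v) == dm))
    stop("u/v dimensions must be length(y) x length(x)")
  if (length(x) > 1L) {
    sp <- diff(x)
    if (max(abs(sp - sp[1])) > 1e-6) stop("lattice must be uniformly spaced")
  }
  if (is.null(corr)) corr <- matrix(1, dm[1], dm[2])
  if (is.null(valid)) valid <- matrix(TRUE, dm[1], dm[2])
  if (any(corr > 1 + 1e-9)) stop("correlation coefficients must be <= 1")
  if (any(!is.finite(u[valid])) || any(!is.finite(v[valid])))
    stop("displacements must be finite where valid")
  structure(
    list(x = x, y = y, u = u, v = v, corr = corr, valid = valid,
         pixel_size = pixel_size,
         spacing_px = if (length(x) > 1L) diff(x)[1] else NA_real_,
         spacing_um = if (length(x) > 1L) diff(x)[1] * pixel_size else NA_real_,
         time = time),
    class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d x %d vectors, spacing %.2f px (%.2f um), t = %s h\n",
    length(x$y), length(x$x), x$spacing_px, x$spacing_um, format(x$time)))
  cat(sprintf("  |u| max %.3f um, mean corr %.3f, %d invalid\n",
              max(sqrt(x$u^2 + x$v^2)), mean(x$corr), sum(!x$valid)))
  invisible(x)
}

#' @describeIn displacement_field Long-format data frame with px and um
#'   columns (`x_px, y_px, u_px, v_px, u_um, v_um, corr, valid, time_h`).
#' @param row.names,optional,... Passed through for compatibility; unused.
#' @export
as.data.frame.displacement_field <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  g <- expand.grid(y_px = x$y, x_px = x$x)
  data.frame(
    x_px = g$x_px, y_px = g$y_px,
    u_px = as.vector(x$u) / x$pixel_size, v_px = as.vector(x$v) / x$pixel_size,
    u_um = as.vector(x$u), v_um = as.vector(x$v),
    corr = as.vector(x$corr), valid = as.vector(x$valid),
    time_h = x$time)
}

# Lattice of window centers for a given window size/spacing within an image.
piv_grid <- function(dim_img, w, spacing) {
  ny <- dim_img[1]; nx <- dim_img[2]
  x0 <- seq(1L, nx - w + 1L, by = spacing)
  y0 <- seq(1L, ny - w + 1L, by = spacing)
  list(x0 = x0, y0 = y0, cx = x0 + (w - 1) / 2, cy = y0 + (w - 1) / 2)
}

#' Align an image stack to a reference frame
#'
#' Estimates the whole-frame rigid translation of every frame relative to the
#' reference by normalized cross-correlation with subpixel (three-point
#' Gaussian) peak refinement, and resamples each frame onto the reference
#' frame to remove experimental drift.
#'
#' @param stack List of numeric matrices (frames), identical dimensions.
#' @param reference_index Index of the reference frame (default 1, the frame
#'   acquired at induction time).
#' @return List with `stack` (aligned frames) and `shifts` (data frame
#'   `frame, shift_x_px, shift_y_px` of the estimated drifts).
#' @export
align_to_reference <- function(stack, reference_index = 1L) {
  if (length(stack) < 2L) stop("need at least 2 frames to align")
  ref <- stack[[reference_index]]
  md <- floor(min(dim(ref)) / 4)
  shifts <- matrix(0, length(stack), 2)
  aligned <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    fr <- stack[[i]]
    if (!all(dim(fr) == dim(ref))) stop("frames differ in shape")
    if (i == reference_index) { aligned[[i]] <- fr; next }
    pk <- ncc_peak(ref, fr, md)
    if (is.null(pk)) {
      warning(sprintf("frame %d is featureless; assuming zero drift", i))
      pk <- list(dx = 0, dy = 0)
    }
    shifts[i, ] <- c(pk$dx, pk$dy)
    aligned[[i]] <- if (pk$dx == 0 && pk$dy == 0) fr else
      translate_img(fr, pk$dx, pk$dy)
  }
  list(stack = aligned,
       shifts = data.frame(frame = seq_along(stack),
                           shift_x_px = shifts[, 1], shift_y_px = shifts[, 2]))
}

#' Iterative multi-pass PIV
#'
#' Windowed normalized cross-correlation between a reference and a current
#' bead image, with the interrogation window made progressively smaller over
#' passes. Each pass uses the previous pass's field (3x3 median-smoothed and
#' bilinearly interpolated) as a predictor to offset the interrogation window
#' in the current image, so the correlation search only has to resolve the
#' residual. Correlation peaks are refined to subpixel precision by a
#' three-point Gaussian fit; the search range per pass is a quarter window.
#'
#' @param reference,current Numeric matrices of identical shape.
#' @param cfg A [piv_config()].
#' @return A [displacement_field()] on the final-pass lattice (displacements
#'   in um = px x `pixel_size`). Degenerate windows (flat intensity) are
#'   flagged invalid with corr 0.
#' @export
iterative_piv <- function(reference, current, cfg = piv_config()) {
  if (!all(dim(reference) == dim(current))) stop("images must share shape")
  if (cfg$window_sizes[1] > min(dim(reference)) / 2)
    stop("largest window exceeds half the image size")
  prev <- NULL
  for (k in seq_along(cfg$window_sizes)) {
    w <- cfg$window_sizes[k]
    last <- k == length(cfg$window_sizes)
    spacing <- if (last && cfg$final_spacing_rule == "half-window") w %/% 2L else w
    prev <- piv_pass(reference, current, w, spacing, prev, refine = last)
  }
  displacement_field(
    x = prev$cx, y = prev$cy,
    u = prev$u * cfg$pixel_size, v = prev$v * cfg$pixel_size,
    corr = prev$corr, valid = prev$valid,
    pixel_size = cfg$pixel_size)
}

# One correlation pass; `pred` is the previous pass result (px) or NULL.
# With `refine`, the discrete peak estimate is polished by iterative
# fractional window shifting: the current window is re-sampled (bilinear)
# at the running estimate and re-correlated, driving the residual - and the
# peak-fit bias that grows with it - towards zero.
piv_pass <- function(reference, current, w, spacing, pred, refine = FALSE) {
  dm <- dim(reference)
  g <- piv_grid(dm, w, spacing)
  nyv <- length(g$y0); nxv <- length(g$x0)
  u <- matrix(0, nyv, nxv); v <- matrix(0, nyv, nxv)
  corr <- matrix(0, nyv, nxv); valid <- matrix(TRUE, nyv, nxv)
  if (!is.null(pred)) {
    pu <- median3(pred$u); pv <- median3(pred$v)
  }
  md <- max(2L, w %/% 4L)
  for (i in seq_len(nyv)) {
    for (j in seq_len(nxv)) {
      x0 <- g$x0[j]; y0 <- g$y0[i]
      dx0 <- 0L; dy0 <- 0L
      if (!is.null(pred)) {
        dx0 <- as.integer(round(bilin_at(pred$cx, pred$cy, pu, g$cx[j], g$cy[i])))
        dy0 <- as.integer(round(bilin_at(pred$cx, pred$cy, pv, g$cx[j], g$cy[i])))
      }
      x0c <- min(max(x0 + dx0, 1L), dm[2] - w + 1L)
      y0c <- min(max(y0 + dy0, 1L), dm[1] - w + 1L)
      ref_w <- reference[y0:(y0 + w - 1L), x0:(x0 + w - 1L)]
      cur_w <- current[y0c:(y0c + w - 1L), x0c:(x0c + w - 1L)]
      pk <- ncc_peak(ref_w, cur_w, md)
      if (is.null(pk)) {
        valid[i, j] <- FALSE
        u[i, j] <- if (is.null(pred)) 0 else (x0c - x0)
        v[i, j] <- if (is.null(pred)) 0 else (y0c - y0)
        next
      }
      dx_tot <- (x0c - x0) + pk$dx
      dy_tot <- (y0c - y0) + pk$dy
      cval <- pk$corr
      if (refine) {
        for (it in 1:2) {
          cur_r <- window_at(current, x0 + dx_tot, y0 + dy_tot, w)
          pk2 <- ncc_peak(ref_w, cur_r, 2L)
          if (is.null(pk2)) break
          dx_tot <- dx_tot + pk2$dx
          dy_tot <- dy_tot + pk2$dy
          cval <- pk2$corr
          if (abs(pk2$dx) < 0.005 && abs(pk2$dy) < 0.005) break
        }
      }
      u[i, j] <- dx_tot
      v[i, j] <- dy_tot
      corr[i, j] <- cval
    }
  }
  list(cx = g$cx, cy = g$cy, u = u, v = v, corr = corr, valid = valid)
}

#' Threshold-validate a displacement field and fill rejected vectors
#'
#' Vectors whose correlation coefficient falls below the configured threshold
#' are marked invalid and replaced by the median of their valid 8-neighbors,
#' iterating until no further vector can be filled. If more than half the
#' vectors fail validation the field is additionally tagged with a
#' quality-failure flag (attribute `quality_failed`).
#'
#' @param field A [displacement_field()].
#' @param cfg A [piv_config()]; supplies the correlation threshold.
#' @return The field with invalid vectors replaced; attributes `n_replaced`
#'   and `quality_failed` record what happened.
#' @export
validate_and_fill <- function(field, cfg = piv_config()) {
  bad <- field$corr < cfg$correlation_threshold | !field$valid
  quality_failed <- mean(bad) > 0.5
  if (quality_failed)
    warning(sprintf("%.0f%% of vectors failed validation", 100 * mean(bad)))
  u <- field$u; v <- field$v
  u[bad] <- NA_real_; v[bad] <- NA_real_
  n_replaced <- 0L
  repeat {
    todo <- which(is.na(u), arr.ind = TRUE)
    if (nrow(todo) == 0L) break
    filled_any <- FALSE
    unew <- u; vnew <- v
    for (r in seq_len(nrow(todo))) {
      i <- todo[r, 1]; j <- todo[r, 2]
      ii <- max(1L, i - 1L):min(nrow(u), i + 1L)
      jj <- max(1L, j - 1L):min(ncol(u), j + 1L)
      nb_u <- u[ii, jj]; nb_v <- v[ii, jj]
      if (any(!is.na(nb_u))) {
        unew[i, j] <- stats::median(nb_u, na.rm = TRUE)
        vnew[i, j] <- stats::median(nb_v, na.rm = TRUE)
        filled_any <- TRUE
        n_replaced <- n_replaced + 1L
      }
    }
    u <- unew; v <- vnew
    if (!filled_any) break
  }
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  out <- field
  out$u <- u; out$v <- v
  out$valid <- !bad
  attr(out, "n_replaced") <- n_replaced
  attr(out, "quality_failed") <- quality_failed
  out
}
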