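#' Read a multi-page TIFF image stack
#'
#' @param path Path to a multi-page TIFF.
#' @param pixel_size Pixel size (um) attached to the stack as an attribute.
#' @param dt Frame interval (hours) attached as an attribute.
#' @return List of numeric matrices (16-bit data is returned as exact
#'   integers), with attributes `pixel_size` and `dt`.
#' @export
read_image_stack <- function(path, pixel_size = 0.3086, dt = 0.5) {
  if (!file.exists(path)) stop("image stack not found: ", path)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    storage.mode(f) <- "double"
    f
  })
  d1 <- dim(frames[[1]])
  for (f in frames)
    if (!all(dim(f) == d1)) stop("inconsistent frame shapes in ", path)
  attr(frames, "pixel_size") <- pixel_size
  attr(frames, "dt") <- dt
  frames
}

#' Write an image stack as 16-bit multi-page TIFF
#'
#' Frames with values above 1 are treated as 16-bit counts (written exactly);
#' frames in \[0, 1\] are scaled to the full 16-bit range. Values are clamped.
#'
#' @param stack List of numeric matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  pages <- lapply(stack, function(f) {
    if (max(f) > 1) f <- f / 65535
    pmin(pmax(f, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write displacement fields as tidy CSV
#'
#' Long-format interchange with columns `x_px, y_px, u_px, v_px, u_um, v_um,
#' corr, valid, time_h` (one block per timepoint). Traction CSVs mirror the
#' schema with `t_x_Pa, t_y_Pa` columns.
#'
#' @param fields A [displacement_field()] or list of them.
#' @param path CSV path.
#' @return `path` invisibly (writers); a list of fields (readers).
#' @export
write_displacement_csv <- function(fields, path) {
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  df <- do.call(rbind, lapply(fields, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displacement_csv
#' @param pixel_size Pixel size (um) for reconstructing fields.
#' @export
read_displacement_csv <- function(path, pixel_size = 0.3086) {
  if (!file.exists(path)) stop("displacement CSV not found: ", path)
  df <- utils::read.csv(path)
  lapply(split(df, df$time_h), function(b) {
    x <- sort(unique(b$x_px)); y <- sort(unique(b$y_px))
    ord <- order(b$x_px, b$y_px)
    b <- b[ord, ]
    displacement_field(
      x, y,
      u = matrix(b$u_um, length(y), length(x)),
      v = matrix(b$v_um, length(y), length(x)),
      corr = matrix(b$corr, length(y), length(x)),
      valid = matrix(b$valid, length(y), length(x)),
      pixel_size = pixel_size, time = b$time_h[1])
  })
}

#' @rdname write_displacement_csv
#' @param tractions A [traction_field()] or list of them.
#' @export
write_traction_csv <- function(tractions, path) {
  if (inherits(tractions, "traction_field")) tractions <- list(tractions)
  df <- do.call(rbind, lapply(tractions, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displacement_csv
#' @export
read_traction_csv <- function(path, pixel_size = 0.3086) {
  if (!file.exists(path)) stop("traction CSV not found: ", path)
  df <- utils::read.csv(path)
  lapply(split(df, df$time_h), function(b) {
    x <- sort(unique(b$x_px)); y <- sort(unique(b$y_px))
    ord <- order(b$x_px, b$y_px)
    b <- b[ord, ]
    traction_field(
      x, y,
      tx = matrix(b$t_x_Pa, length(y), length(x)),
      ty = matrix(b$t_y_Pa, length(y), length(x)),
      pixel_size = pixel_size, time = b$time_h[1])
  })
}
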