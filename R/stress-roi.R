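#' Region of interest around a (candidate) fusion site
#'
#' A labeled patch of the monolayer — syncytial (fused) or mononucleated —
#' represented as a pixel mask. The areal centroid, computed from the
#' original (undilated) region, defines the origin of the radial/tangential
#' stress decomposition; dilation only widens the sampling region.
#'
#' @param mask Logical matrix (TRUE inside the region), image resolution.
#' @param label `"syncytial"` or `"mononucleated"`.
#' @param fused_fraction Annotated fused fraction of the region (e.g.
#'   0.75-0.80 for selected syncytial patches, 0.25-0.30 for mononucleated
#'   comparison patches). Carried as metadata, never computed here.
#' @param pixel_size Pixel size in um.
#' @return Object of class `region_of_interest` with fields `mask`, `label`,
#'   `fused_fraction`, `centroid_px` (x, y), `area_px`, `area_um2`,
#'   `pixel_size`, `dilation_px`.
#' @export
region_of_interest <- function(mask, label = c("syncytial", "mononucleated"),
                               fused_fraction = NA_real_,
                               pixel_size = 0.3086) {
  label <- match.arg(label)
  mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  structure(
    list(mask = mask, label = label, fused_fraction = fused_fraction,
         centroid_px = centroid, area_px = sum(mask),
         area_um2 = sum(mask) * pixel_size^2,
         pixel_size = pixel_size, dilation_px = 0L),
    class = "region_of_interest")
}

#' Disk-shaped ROI helper
#'
#' @param center Disk center `(x, y)` in px.
#' @param radius Disk radius in px.
#' @param dim_img Image dimensions `c(ny, nx)`.
#' @inheritParams region_of_interest
#' @return A [region_of_interest()].
#' @export
roi_disk <- function(center, radius, dim_img,
                     label = c("syncytial", "mononucleated"),
                     fused_fraction = NA_real_, pixel_size = 0.3086) {
  xs <- matrix(seq_len(dim_img[2]), dim_img[1], dim_img[2], byrow = TRUE)
  ys <- matrix(seq_len(dim_img[1]), dim_img[1], dim_img[2])
  mask <- (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
  region_of_interest(mask, label, fused_fraction, pixel_size)
}

#' Dilate an ROI to include neighboring cells
#'
#' Dilates the region mask by a Euclidean disk, widening the stress-sampling
#' region to empirically include 1-2 cell widths outside the fused patch
#' (default 80 px). The areal centroid is kept from the ORIGINAL region: the
#' centroid marks the fusion site, the dilation only changes where stresses
#' are sampled. A dilation that runs into the image border is clipped with a
#' warning.
#'
#' @param roi A [region_of_interest()].
#' @param pixels Dilation radius in px (default 80).
#' @return The dilated [region_of_interest()]; `centroid_px` unchanged,
#'   `dilation_px` recording the total applied dilation.
#' @export
dilate_roi <- function(roi, pixels = 80L) {
  pixels <- as.integer(pixels)
  if (pixels < 0L) stop("`pixels` must be >= 0")
  if (pixels == 0L) return(roi)
  brush <- EBImage::makeBrush(2L * pixels + 1L, shape = "disc")
  dil <- EBImage::dilate(roi$mask * 1, brush) > 0
  edge <- any(dil[1, ]) || any(dil[nrow(dil), ]) ||
    any(dil[, 1]) || any(dil[, ncol(dil)])
  if (edge) warning("dilated ROI clipped at image bounds")
  out <- roi
  out$mask <- dil
  out$area_px <- sum(dil)
  out$area_um2 <- sum(dil) * roi$pixel_size^2
  out$dilation_px <- roi$dilation_px + pixels
  out
}

#' Radial/tangential decomposition of a traction field about an ROI centroid
#'
#' For every lattice point of the traction field inside the (typically
#' dilated) ROI mask, the stress vector S is decomposed along the unit ray
#' from the region's areal centroid (radial, `S_R = S . r_hat`) and its
#' perpendicular (tangential, `S_T = S . t_hat`). Sign convention: `S_R > 0`
#' points away from the centroid, so compressive stresses directed into the
#' region appear as negative radial means. The spatial mean of signed `S_R`
#' and of `|S_T|` (absolute value taken before averaging) are returned. A
#' lattice point coincident with the centroid is excluded.
#'
#' @param traction A [traction_field()].
#' @param roi A [region_of_interest()] (use [dilate_roi()] first to match the
#'   80-px-enlarged sampling of the reference analysis).
#' @return Object of class `stress_decomposition`: `time`, `mean_radial`
#'   (Pa, signed), `mean_abs_tangential` (Pa), `n` vectors used, plus the
#'   per-vector `radial` and `tangential` components.
#' @export
decompose_field <- function(traction, roi) {
  cx <- roi$centroid_px["x"]; cy <- roi$centroid_px["y"]
  xi <- round(rep(traction$x, each = length(traction$y)))
  yi <- round(rep(traction$y, times = length(traction$x)))
  keep <- xi >= 1 & xi <= ncol(roi$mask) & yi >= 1 & yi <= nrow(roi$mask)
  keep[keep] <- roi$mask[cbind(yi[keep], xi[keep])]
  gx <- rep(traction$x, each = length(traction$y))
  gy <- rep(traction$y, times = length(traction$x))
  dx <- gx - cx; dy <- gy - cy
  r <- sqrt(dx^2 + dy^2)
  keep <- keep & r > 1e-9
  if (!any(keep)) stop("no traction lattice points fall inside the ROI")
  rx <- dx[keep] / r[keep]; ry <- dy[keep] / r[keep]
  tx <- as.vector(traction$tx)[keep]; ty <- as.vector(traction$ty)[keep]
  sr <- tx * rx + ty * ry
  st <- -tx * ry + ty * rx # r_hat rotated +90 degrees
  structure(
    list(time = traction$time,
         mean_radial = mean(sr),
         mean_abs_tangential = mean(abs(st)),
         n = sum(keep), radial = sr, tangential = st),
    class = "stress_decomposition")
}

#' Stress decomposition time series for one ROI
#'
#' Runs [decompose_field()] on every traction field of a time series,
#' returning a tidy data frame (one row per timepoint).
#'
#' @param tractions List of [traction_field()]s with `time` set (hours).
#' @param roi A [region_of_interest()].
#' @return Data frame of class `stress_timeseries` with columns
#'   `time_h`, `mean_radial_pa`, `mean_abs_tangential_pa`, `n_vectors`;
#'   the ROI label is carried in attribute `label`.
#' @export
stress_timeseries <- function(tractions, roi) {
  rows <- lapply(tractions, function(tf) {
    d <- decompose_field(tf, roi)
    data.frame(time_h = d$time, mean_radial_pa = d$mean_radial,
               mean_abs_tangential_pa = d$mean_abs_tangential,
               n_vectors = d$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time_h), , drop = FALSE]
  if (any(diff(out$time_h) <= 0)) stop("times must be strictly increasing")
  class(out) <- c("stress_timeseries", "data.frame")
  attr(out, "label") <- roi$label
  out
}

#' Average stresses over the fusion window
#'
#' Unweighted mean of the radial and absolute-tangential stress series over
#' timepoints with `t_start <= t <= t_end`. The default 12-48 h window skips
#' the early onset transient so that ROIs are compared on their sustained
#' stress state.
#'
#' @param series A [stress_timeseries()] data frame.
#' @param t_start,t_end Window bounds in hours (defaults 12 and 48).
#' @return List with `mean_radial`, `mean_abs_tangential`, `n_timepoints`.
#' @export
aggregate_window <- function(series, t_start = 12, t_end = 48) {
  sel <- series$time_h >= t_start & series$time_h <= t_end
  if (!any(sel)) stop("no timepoints fall in the aggregation window")
  list(mean_radial = mean(series$mean_radial_pa[sel]),
       mean_abs_tangential = mean(series$mean_abs_tangential_pa[sel]),
       n_timepoints = sum(sel))
}

#' Compare syncytial vs. mononucleated regions
#'
#' Two-sided independent two-sample Student's t-test (equal variance) on
#' per-ROI aggregated stress values, plus group means and SDs for reporting.
#' Degenerate inputs follow fixed conventions: both groups constant with
#' equal means gives `t = 0, p = 1`; both constant with different means gives
#' complete separation (`p = 0`).
#'
#' @param syncytial,mononucleated Numeric vectors of per-ROI values
#'   (each n >= 2).
#' @return List with `t`, `p`, `df`, `mean_syncytial`, `mean_mononucleated`,
#'   `sd_syncytial`, `sd_mononucleated`.
#' @export
compare_regions <- function(syncytial, mononucleated) {
  if (length(syncytial) < 2L || length(mononucleated) < 2L)
    stop("each group needs n >= 2")
  n1 <- length(syncytial); n2 <- length(mononucleated)
  df <- n1 + n2 - 2
  s1 <- stats::sd(syncytial); s2 <- stats::sd(mononucleated)
  if (s1 == 0 && s2 == 0) {
    eq <- mean(syncytial) == mean(mononucleated)
    tt <- if (eq) 0 else sign(mean(syncytial) - mean(mononucleated)) * Inf
    pp <- if (eq) 1 else 0
  } else {
    ht <- stats::t.test(syncytial, mononucleated, var.equal = TRUE)
    tt <- unname(ht$statistic); pp <- ht$p.value
  }
  list(t = tt, p = pp, df = df,
       mean_syncytial = mean(syncytial),
       mean_mononucleated = mean(mononucleated),
       sd_syncytial = s1, sd_mononucleated = s2)
}

#' Read / write ROIs as polygon JSON
#'
#' ROIs can be exchanged as JSON polygons: a list of objects with fields
#' `label`, `fused_fraction` and `polygon` (list of `(x, y)` pixel vertices).
#' `read_roi_json()` rasterizes each polygon onto the given image dimensions.
#'
#' @param path JSON file path.
#' @param dim_img Image dimensions `c(ny, nx)` for rasterization.
#' @param pixel_size Pixel size in um.
#' @return A list of [region_of_interest()]s.
#' @export
read_roi_json <- function(path, dim_img, pixel_size = 0.3086) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  specs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(specs, function(s) {
    poly <- s$polygon
    if (!is.matrix(poly)) poly <- do.call(rbind, lapply(poly, unlist))
    if (ncol(poly) != 2L) stop("polygon vertices must be (x, y) pairs")
    xs <- matrix(seq_len(dim_img[2]), dim_img[1], dim_img[2], byrow = TRUE)
    ys <- matrix(seq_len(dim_img[1]), dim_img[1], dim_img[2])
    inside <- mgcv::in.out(rbind(poly, poly[1, ]),
                           cbind(as.vector(xs), as.vector(ys)))
    mask <- matrix(inside, dim_img[1], dim_img[2])
    region_of_interest(mask, s$label,
                       fused_fraction = s$fused_fraction %||% NA_real_,
                       pixel_size = pixel_size)
  })
}

#' @rdname read_roi_json
#' @param rois List of lists with `label`, `fused_fraction`, `polygon`.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
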