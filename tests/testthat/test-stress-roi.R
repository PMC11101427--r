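# A unit lattice (1 px spacing, pixel_size 1 um) keeps geometry transparent.
unit_traction <- function(n, fx, fy) {
  gx <- matrix(1:n, n, n, byrow = TRUE)
  gy <- matrix(1:n, n, n)
  traction_field(1:n, 1:n, fx(gx, gy), fy(gx, gy), pixel_size = 1)
}

test_that("dilation grows a disk by its radius and preserves the centroid", {
  roi <- roi_disk(c(200, 200), 50, c(400, 400), "syncytial", pixel_size = 1)
  expect_identical(dilate_roi(roi, 0), roi)
  big <- dilate_roi(roi, 80)
  expect_equal(unname(big$centroid_px), c(200, 200))
  expect_equal(big$area_px / (pi * 130^2), 1, tolerance = 0.02)
  expect_gte(big$area_px, roi$area_px)
  expect_equal(big$dilation_px, 80L)
})

test_that("dilation past the image border clips with a warning", {
  roi <- roi_disk(c(30, 30), 20, c(100, 100), "syncytial", pixel_size = 1)
  expect_warning(out <- dilate_roi(roi, 40), "clipped")
  expect_lt(out$area_px, pi * 60^2)
})

test_that("stress aligned with / orthogonal to the centroid ray decomposes exactly", {
  n <- 41
  cn <- 21 # symmetric mask centroid at (21, 21)
  mask <- matrix(FALSE, n, n)
  mask[(cn - 8):(cn + 8), (cn - 8):(cn + 8)] <- TRUE
  roi <- region_of_interest(mask, "syncytial", pixel_size = 1)
  # field nonzero only due east of the centroid
  east_only <- function(val_x, val_y) {
    tx <- matrix(0, n, n); ty <- matrix(0, n, n)
    tx[cn, cn + 5] <- val_x; ty[cn, cn + 5] <- val_y
    traction_field(1:n, 1:n, tx, ty, pixel_size = 1)
  }
  d1 <- decompose_field(east_only(1, 0), roi)
  expect_equal(max(d1$radial), 1)
  expect_equal(sum(abs(d1$tangential)), 0)
  d2 <- decompose_field(east_only(0, 1), roi)
  expect_equal(sum(abs(d2$radial)), 0)
  expect_equal(max(abs(d2$tangential)), 1)
})

test_that("a purely inward unit field on an annulus gives mean_radial -1", {
  n <- 41
  tf <- unit_traction(n,
    function(gx, gy) -ifelse(gx == 21 & gy == 21, 0, (gx - 21) / sqrt((gx - 21)^2 + (gy - 21)^2)),
    function(gx, gy) -ifelse(gx == 21 & gy == 21, 0, (gy - 21) / sqrt((gx - 21)^2 + (gy - 21)^2)))
  gx <- matrix(1:n, n, n, byrow = TRUE); gy <- matrix(1:n, n, n)
  r <- sqrt((gx - 21)^2 + (gy - 21)^2)
  roi <- region_of_interest(r >= 5 & r <= 15, "syncytial", pixel_size = 1)
  d <- decompose_field(tf, roi)
  expect_equal(d$mean_radial, -1)
  expect_equal(d$mean_abs_tangential, 0)
  # energy conservation per vector, to machine precision
  expect_lt(max(abs(d$radial^2 + d$tangential^2 - 1)), 1e-12)
  # negating the field flips the radial sign only
  tf_neg <- traction_field(tf$x, tf$y, -tf$tx, -tf$ty, pixel_size = 1)
  dn <- decompose_field(tf_neg, roi)
  expect_equal(dn$mean_radial, 1)
  expect_equal(dn$mean_abs_tangential, 0)
})

test_that("the decomposition is invariant under 90-degree rotation of field and ROI", {
  set.seed(3)
  n <- 41
  tx <- matrix(rnorm(n * n), n, n); ty <- matrix(rnorm(n * n), n, n)
  tf <- traction_field(1:n, 1:n, tx, ty, pixel_size = 1)
  gx <- matrix(1:n, n, n, byrow = TRUE); gy <- matrix(1:n, n, n)
  mask <- (gx - 21)^2 / 2 + (gy - 21)^2 <= 90 # asymmetric (elliptic) ROI
  roi <- region_of_interest(mask, "syncytial", pixel_size = 1)
  d <- decompose_field(tf, roi)
  tf_rot <- traction_field(1:n, 1:n, -rot90_mat(ty), rot90_mat(tx),
                           pixel_size = 1)
  roi_rot <- region_of_interest(rot90_mat(mask), "syncytial", pixel_size = 1)
  d_rot <- decompose_field(tf_rot, roi_rot)
  expect_equal(d_rot$mean_radial, d$mean_radial, tolerance = 1e-12)
  expect_equal(d_rot$mean_abs_tangential, d$mean_abs_tangential,
               tolerance = 1e-12)
})

test_that("window aggregation is the unweighted mean over included timepoints", {
  times <- seq(0, 48, by = 0.5)
  ser <- structure(
    data.frame(time_h = times, mean_radial_pa = times,
               mean_abs_tangential_pa = 2 * times, n_vectors = 9L),
    class = c("stress_timeseries", "data.frame"))
  ag <- aggregate_window(ser)
  expect_equal(ag$mean_radial, 30)
  expect_equal(ag$n_timepoints, 73L)
  # constant series aggregates to the constant
  ser$mean_radial_pa <- -2.5
  expect_equal(aggregate_window(ser, 0, 48)$mean_radial, -2.5)
  expect_error(aggregate_window(ser, 100, 200), "window")
})

test_that("group comparison follows the fixed degenerate conventions", {
  same <- compare_regions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  flat <- compare_regions(c(0, 0, 0), c(0, 0, 0))
  expect_equal(flat$p, 1)
  sep <- compare_regions(c(0, 0, 0), c(1, 1, 1))
  expect_lt(sep$p, 0.05)
  # agrees with the standard equal-variance t-test on regular data
  set.seed(1)
  a <- rnorm(7, -2); b <- rnorm(7, 0)
  ht <- t.test(a, b, var.equal = TRUE)
  got <- compare_regions(a, b)
  expect_equal(got$t, unname(ht$statistic))
  expect_equal(got$p, ht$p.value)
  expect_error(compare_regions(1, c(1, 2)), "n >= 2")
})

test_that("polygon ROIs survive a JSON write/read roundtrip", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  sq <- list(list(label = "syncytial", fused_fraction = 0.78,
                  polygon = list(c(10, 10), c(40, 10), c(40, 40), c(10, 40))))
  write_roi_json(sq, tmp)
  rois <- read_roi_json(tmp, c(60, 60), pixel_size = 1)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$label, "syncytial")
  expect_equal(rois[[1]]$fused_fraction, 0.78)
  expect_equal(unname(rois[[1]]$centroid_px), c(25, 25), tolerance = 0.05)
  expect_equal(rois[[1]]$area_px, 30^2, tolerance = 0.15)
})
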