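test_that("generators are bit-deterministic under a fixed seed", {
  spec <- bead_image_spec(image_size = 128, seed = 21)
  f <- function(x, y) list(u = 0.5 * sin(x / 30), v = rep(0, length(x)))
  a <- make_bead_pair(spec, f)
  b <- make_bead_pair(spec, f)
  expect_identical(a$reference, b$reference)
  expect_identical(a$deformed, b$deformed)
  t1 <- make_spheroid_track(seed = 5)
  t2 <- make_spheroid_track(seed = 5)
  expect_identical(t1, t2)
  l1 <- make_fusion_labels(40, 2, c(3L, 5L), seed = 8)
  l2 <- make_fusion_labels(40, 2, c(3L, 5L), seed = 8)
  expect_identical(l1, l2)
})

test_that("a zero field yields bit-identical reference and deformed images", {
  spec <- bead_image_spec(image_size = 128, seed = 1)
  p <- make_bead_pair(spec, function(x, y) list(u = rep(0, length(x)),
                                                v = rep(0, length(x))))
  expect_identical(p$reference, p$deformed)
  expect_equal(max(abs(c(p$truth$u, p$truth$v))), 0)
})

test_that("ground truth is the analytic field sampled on the PIV lattice", {
  spec <- bead_image_spec(image_size = 256, seed = 2)
  p <- make_bead_pair(spec, function(x, y) list(u = rep(5, length(x)),
                                                v = rep(0, length(x))))
  expect_true(all(p$truth$u == 5 * spec$pixel_size))
  expect_true(all(p$truth$v == 0))
  expect_equal(diff(p$truth$x)[1], 48)
})

test_that("excessive displacements are refused with a diagnostic", {
  spec <- bead_image_spec(image_size = 256, seed = 3)
  expect_error(
    make_bead_pair(spec, function(x, y) list(u = rep(20, length(x)),
                                             v = rep(0, length(x)))),
    "quarter")
})

test_that("patches outside the field extent are refused", {
  expect_error(
    contraction_scenario(c(5, 5), patch_radius = 25, field_extent = 512),
    "inside")
})

test_that("a zero-traction movie has all frames identical to frame 1", {
  scen <- contraction_scenario(c(80, 80), patch_radius = 25,
                               peak_traction = 0, field_extent = 512)
  mv <- make_contraction_movie(scen, times = c(0, 4, 8, 12),
                               bead_spec = bead_image_spec(512, seed = 6))
  for (i in 2:4) expect_identical(mv$stack[[i]], mv$stack[[1]])
  expect_equal(max(abs(mv$truth[[4]]$tx)), 0)
})

test_that("contraction-movie tractions are zero before onset and inward after", {
  scen <- contraction_scenario(c(80, 80), patch_radius = 20,
                               peak_traction = 40, onset_time = 6,
                               field_extent = 512, seed = 2)
  mv <- make_contraction_movie(scen, times = c(0, 4, 8, 24))
  expect_equal(max(abs(mv$truth[[2]]$tx)), 0) # t = 4 < onset
  plateau <- mv$truth[[4]]
  expect_gt(max(sqrt(plateau$tx^2 + plateau$ty^2)), 0)
  # mean radial traction over the patch ROI is negative by construction
  roi <- roi_disk(c(80, 80) / 0.3086, 30 / 0.3086, c(512, 512),
                  "syncytial", pixel_size = 0.3086)
  d <- decompose_field(plateau, roi)
  expect_lt(d$mean_radial, 0)
  # ramp: halfway between onset and onset + 2 h gives half the plateau
  mv2 <- make_contraction_movie(scen, times = c(0, 7, 24))
  expect_equal(mv2$truth[[2]]$tx, 0.5 * mv2$truth[[3]]$tx)
})

test_that("fusion-label masks realize the requested tallies", {
  lab <- make_fusion_labels(100, 0, integer(), seed = 1)
  expect_identical(unclass(lab$counts),
                   unclass(fusion_counts(100, 0, 0, 0)))
  one <- make_fusion_labels(50, 1, 50L, seed = 2)
  expect_identical(one$counts$F, 50L)
  expect_identical(one$counts$S, 1L)
  # syndecan fraction marks whole syncytia
  half <- make_fusion_labels(60, 4, c(5L, 5L, 5L, 5L),
                             fraction_syndecan = 0.5, seed = 3)
  expect_identical(half$counts$FS, 10L)
})

test_that("spheroid tracks follow the elastic equilibrium with noise on t > 0 only", {
  trk <- make_spheroid_track(d0 = 400, pressure = 1000, noise_sd = 0)
  eps <- strain_from_pressure(1000, gel_calibration()$youngs_modulus, 0.457)
  expect_equal(trk$diameter_um[-1], rep(400 * (1 - eps), 5))
  noisy <- make_spheroid_track(d0 = 400, pressure = 1000, noise_sd = 2,
                               seed = 3)
  expect_equal(noisy$diameter_um[1], 400) # reference is noise-free
  expect_false(any(noisy$diameter_um[-1] == 400 * (1 - eps)))
  expect_equal(noisy$area_um2, pi * (noisy$diameter_um / 2)^2)
})
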