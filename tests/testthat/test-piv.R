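spec <- bead_image_spec(image_size = 512, seed = 11)

test_that("identical images give a zero field with perfect correlation", {
  p <- make_bead_pair(spec, function(x, y) list(u = rep(0, length(x)),
                                                v = rep(0, length(x))))
  f <- iterative_piv(p$reference, p$deformed)
  expect_lt(max(abs(c(f$u, f$v))) / f$pixel_size, 1e-10)
  expect_gt(min(f$corr), 0.99)
})

test_that("uniform shifts (integer and subpixel) are recovered to < 0.1 px", {
  for (shift in list(c(5, 0), c(2.3, -1.4))) {
    p <- make_bead_pair(spec, function(x, y)
      list(u = rep(shift[1], length(x)), v = rep(shift[2], length(x))))
    f <- iterative_piv(p$reference, p$deformed)
    expect_lt(max(abs(f$u / f$pixel_size - shift[1])), 0.1)
    expect_lt(max(abs(f$v / f$pixel_size - shift[2])), 0.1)
  }
})

test_that("final lattice spacing is the final window times the pixel size", {
  p <- make_bead_pair(bead_image_spec(image_size = 256, seed = 2),
                      function(x, y) list(u = rep(1, length(x)),
                                          v = rep(0, length(x))))
  f <- iterative_piv(p$reference, p$deformed)
  expect_equal(f$spacing_px, 48)
  expect_equal(f$spacing_um, 48 * 0.3086)
  cfg_half <- piv_config(final_spacing_rule = "half-window")
  f2 <- iterative_piv(p$reference, p$deformed, cfg_half)
  expect_equal(f2$spacing_px, 24)
})

test_that("a smooth sinusoidal field is recovered and error shrinks with passes", {
  field <- function(x, y) list(u = 2 * sin(2 * pi * x / 300),
                               v = rep(0, length(x)))
  p <- make_bead_pair(spec, field)
  rms_px <- function(cfg) {
    f <- validate_and_fill(iterative_piv(p$reference, p$deformed, cfg), cfg)
    gxy <- expand.grid(y = f$y, x = f$x)
    gt <- field(gxy$x, gxy$y)
    sqrt(mean((f$u / f$pixel_size - gt$u)^2 + (f$v / f$pixel_size - gt$v)^2))
  }
  e3 <- rms_px(piv_config(c(128L, 64L, 48L)))
  e1 <- rms_px(piv_config(128L))
  expect_lt(e3, 0.3)
  expect_lte(e3, e1 + 0.02)
})

test_that("translating both images identically leaves the field unchanged", {
  p <- make_bead_pair(spec, function(x, y)
    list(u = rep(3.2, length(x)), v = rep(-1.1, length(x))))
  roll <- function(m, dy, dx) {
    ny <- nrow(m); nx <- ncol(m)
    m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  f0 <- iterative_piv(p$reference, p$deformed)
  f1 <- iterative_piv(roll(p$reference, 16, -8), roll(p$deformed, 16, -8))
  # compare interior vectors (border windows see wrapped content)
  i <- 3:(length(f0$y) - 2); j <- 3:(length(f0$x) - 2)
  expect_lt(max(abs(f0$u[i, j] - f1$u[i, j])) / f0$pixel_size, 0.05)
  expect_lt(max(abs(f0$v[i, j] - f1$v[i, j])) / f0$pixel_size, 0.05)
})

test_that("swapping reference and current negates the field", {
  p <- make_bead_pair(spec, function(x, y)
    list(u = rep(2.3, length(x)), v = rep(0.7, length(x))))
  fwd <- iterative_piv(p$reference, p$deformed)
  bwd <- iterative_piv(p$deformed, p$reference)
  expect_lt(max(abs(fwd$u + bwd$u)) / fwd$pixel_size, 0.1)
  expect_lt(max(abs(fwd$v + bwd$v)) / fwd$pixel_size, 0.1)
})

test_that("validation leaves good fields alone and repairs isolated outliers", {
  u <- matrix(1.5, 8, 8) * 0.3086
  f <- displacement_field((1:8) * 48, (1:8) * 48, u, u * 0,
                          corr = matrix(0.9, 8, 8))
  out <- validate_and_fill(f)
  expect_identical(out$u, f$u)
  expect_identical(attr(out, "n_replaced"), 0L)
  # one bad vector amid a uniform field is replaced by the uniform value
  corr <- matrix(0.9, 8, 8); corr[4, 5] <- 0.1
  ub <- u; ub[4, 5] <- 99
  f2 <- displacement_field((1:8) * 48, (1:8) * 48, ub, ub * 0, corr = corr)
  out2 <- validate_and_fill(f2)
  expect_equal(out2$u[4, 5], 1.5 * 0.3086)
  expect_identical(attr(out2, "n_replaced"), 1L)
  expect_false(attr(out2, "quality_failed"))
})

test_that("filling 10% invalidated vectors stays close to the smooth field", {
  field <- function(x, y) list(u = 1 + 0.003 * x + 0.3 * sin(2 * pi * x / 800),
                               v = rep(0, length(x)))
  # realistic imaging noise so the fully-valid baseline error is representative
  p <- make_bead_pair(bead_image_spec(image_size = 512, seed = 11,
                                      noise_sd = 0.10), field)
  f <- iterative_piv(p$reference, p$deformed)
  rms_vs_truth <- function(g)
    sqrt(mean((g$u - p$truth$u)^2 + (g$v - p$truth$v)^2))
  err_full <- rms_vs_truth(validate_and_fill(f))
  set.seed(7)
  bad <- sample(length(f$corr), round(0.1 * length(f$corr)))
  f$corr[bad] <- 0.1
  f$u[bad] <- f$u[bad] + 3 # corrupted measurements behind the low peaks
  filled <- validate_and_fill(f)
  expect_identical(attr(filled, "n_replaced"), length(bad))
  expect_lt(rms_vs_truth(filled), 1.5 * err_full)
})

test_that("over 50% invalid vectors raises the quality-failure flag", {
  n <- 6
  corr <- matrix(0.2, n, n); corr[1, 1:3] <- 0.9
  f <- displacement_field((1:n) * 48, (1:n) * 48,
                          matrix(0.3, n, n), matrix(0, n, n), corr = corr)
  expect_warning(out <- validate_and_fill(f), "failed validation")
  expect_true(attr(out, "quality_failed"))
})

test_that("stack alignment recovers constant shifts and linear drift", {
  p <- make_bead_pair(spec, function(x, y)
    list(u = rep(3, length(x)), v = rep(-2, length(x))))
  al <- align_to_reference(list(p$reference, p$deformed), 1L)
  expect_equal(al$shifts$shift_x_px[2], 3, tolerance = 0.1 / 3)
  expect_equal(al$shifts$shift_y_px[2], -2, tolerance = 0.1 / 2)
  # identical frames: zero shift
  al0 <- align_to_reference(list(p$reference, p$reference))
  expect_equal(al0$shifts$shift_x_px, c(0, 0))
  # linear drift 0.5 px/frame: residual drift after alignment < 0.1 px/frame
  drift <- lapply(0:4, function(k) {
    q <- make_bead_pair(spec, function(x, y)
      list(u = rep(0.5 * k, length(x)), v = rep(0, length(x))))
    q$deformed
  })
  ald <- align_to_reference(drift, 1L)
  resid <- ald$shifts$shift_x_px - 0.5 * (0:4)
  expect_lt(max(abs(diff(resid))), 0.1)
})

test_that("a featureless frame aligns with zero shift and a warning", {
  flat <- matrix(0.5, 64, 64)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_warning(al <- align_to_reference(list(img, flat)), "featureless")
  expect_equal(al$shifts$shift_x_px[2], 0)
})
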