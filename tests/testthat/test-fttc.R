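substrate <- elastic_substrate()

test_that("zero traction maps to zero displacement and back", {
  tf <- ring_traction(n = 32, peak = 0)
  u <- forward_displacement(tf, substrate)
  expect_equal(max(abs(c(u$u, u$v))), 0)
  tr <- invert_traction(u, substrate)
  expect_equal(max(abs(c(tr$tx, tr$ty))), 0)
})

test_that("displacements are linear in 1/E and in the traction amplitude", {
  tf <- ring_traction(n = 32)
  u1 <- forward_displacement(tf, substrate)
  u2 <- forward_displacement(tf, elastic_substrate(youngs_modulus = 2 * 3900))
  expect_equal(u2$u, u1$u / 2, tolerance = 1e-12)
  tf2 <- traction_field(tf$x, tf$y, 3 * tf$tx, 3 * tf$ty,
                        pixel_size = tf$pixel_size)
  u3 <- forward_displacement(tf2, substrate)
  expect_equal(u3$v, 3 * u1$v, tolerance = 1e-12)
})

test_that("an opposing traction dipole gives an antisymmetric displacement field", {
  n <- 32; sp <- 48
  x <- (1:n - 0.5) * sp
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  # dipole symmetric about the vertical midline between columns n/2, n/2+1
  tx[n / 2, n / 2 - 4] <- 50
  tx[n / 2, n / 2 + 5] <- -50
  tf <- traction_field(x, x, tx, ty)
  u <- forward_displacement(tf, substrate, fttc_config(zero_pad_factor = 1L))
  mirror <- function(m) m[, n:1]
  # x-component odd, y-component even about the midline
  scale <- max(abs(u$u))
  expect_lt(max(abs(u$u + mirror(u$u))) / scale, 1e-10)
  expect_lt(max(abs(u$v - mirror(u$v))) / scale, 1e-10)
})

test_that("inversion is linear in the displacement field", {
  tfa <- ring_traction(n = 32, R = 100, peak = 30)
  tfb <- ring_traction(n = 32, R = 160, peak = 50)
  ua <- forward_displacement(tfa, substrate)
  ub <- forward_displacement(tfb, substrate)
  cfg <- fttc_config(lambda = 1)
  mix <- displacement_field(ua$x, ua$y, 2 * ua$u - 3 * ub$u,
                            2 * ua$v - 3 * ub$v)
  ta <- invert_traction(ua, substrate, cfg)
  tb <- invert_traction(ub, substrate, cfg)
  tmix <- invert_traction(mix, substrate, cfg)
  expect_equal(tmix$tx, 2 * ta$tx - 3 * tb$tx, tolerance = 1e-10)
  expect_equal(tmix$ty, 2 * ta$ty - 3 * tb$ty, tolerance = 1e-10)
})

test_that("rotating the displacement field by 90 degrees rotates the tractions", {
  tf <- ring_traction(n = 32, R = 100, w = 30)
  # break the ring's own symmetry so the check is non-trivial
  tf$tx[10, 5] <- tf$tx[10, 5] + 20
  u <- forward_displacement(tf, substrate)
  cfg <- fttc_config(lambda = 1e-4)
  tr <- invert_traction(u, substrate, cfg)
  u_rot <- displacement_field(u$x, u$y, -rot90_mat(u$v), rot90_mat(u$u))
  tr_rot <- invert_traction(u_rot, substrate, cfg)
  expect_equal(tr_rot$tx, -rot90_mat(tr$ty), tolerance = 1e-8)
  expect_equal(tr_rot$ty, rot90_mat(tr$tx), tolerance = 1e-8)
})

test_that("net force vanishes when the DC mode is zeroed", {
  tf <- ring_traction(n = 32)
  # bias the input so it carries net force; inversion must remove it
  u <- forward_displacement(tf, substrate)
  tr <- invert_traction(u, substrate)
  net <- sqrt(sum(tr$tx)^2 + sum(tr$ty)^2)
  expect_lt(net / sum(sqrt(tr$tx^2 + tr$ty^2)), 1e-10)
})

test_that("traction magnitude decreases monotonically with lambda on noise", {
  set.seed(5)
  n <- 24
  u <- displacement_field((1:n) * 48, (1:n) * 48,
                          matrix(rnorm(n * n, 0, 0.1), n, n),
                          matrix(rnorm(n * n, 0, 0.1), n, n))
  mags <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    tr <- invert_traction(u, substrate, fttc_config(lambda = l))
    mean(sqrt(tr$tx^2 + tr$ty^2))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_lt(mags[5] / mags[1], 0.1)
})

test_that("lambda = 0 inversion warns about noise amplification", {
  u <- forward_displacement(ring_traction(n = 16), substrate)
  expect_warning(invert_traction(u, substrate, fttc_config(lambda = 0)),
                 "noise")
})

test_that("a time series inverts frame-wise, ordered by time, counts preserved", {
  tf <- ring_traction(n = 16)
  u <- forward_displacement(tf, substrate)
  fields <- lapply(c(1.0, 0.0, 0.5), function(tt) {
    f <- u; f$time <- tt
    f$u <- u$u * tt; f$v <- u$v * tt
    f
  })
  tr <- traction_timeseries(fields, substrate, fttc_config(lambda = 1))
  expect_length(tr, 3)
  expect_equal(vapply(tr, function(t) t$time, numeric(1)), c(0, 0.5, 1))
  expect_equal(max(abs(tr[[1]]$tx)), 0)
  expect_equal(tr[[3]]$tx, 2 * tr[[2]]$tx, tolerance = 1e-10)
})
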