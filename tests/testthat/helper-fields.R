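# Shared fixture builders (all synthetic, generated at test time).

# Inward-pointing Gaussian-ring traction field on an n x n lattice with
# spacing sp px; peak in Pa, ring radius R and width w in um.
ring_traction <- function(n = 64, sp = 48, R = 120, w = 40, peak = 40,
                          pixel_size = 0.3086) {
  x <- (1:n - 0.5) * sp
  gx <- matrix(x, n, n, byrow = TRUE)
  gy <- matrix(x, n, n)
  dx <- (gx - mean(x)) * pixel_size
  dy <- (gy - mean(x)) * pixel_size
  rho <- sqrt(dx^2 + dy^2)
  mag <- peak * exp(-(rho - R)^2 / (2 * w^2))
  tx <- -mag * dx / pmax(rho, 1e-9)
  ty <- -mag * dy / pmax(rho, 1e-9)
  traction_field(x, x, tx, ty, pixel_size = pixel_size)
}

# Rotate matrices / fields by +90 degrees on a square lattice.
rot90_mat <- function(m) t(m)[, nrow(m):1]

rel_l2 <- function(ax, ay, bx, by) {
  sqrt(sum((ax - bx)^2 + (ay - by)^2) / sum(bx^2 + by^2))
}
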