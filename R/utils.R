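# Internal numeric helpers shared across modules.

# DFT sample frequencies (cycles per unit), numpy-style ordering.
fftfreq <- function(n, d = 1) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# Inverse FFT returning the real part, normalized.
ifft_re <- function(z) Re(stats::fft(z, inverse = TRUE)) / length(z)

# Bilinear interpolation of z (rows = yg, cols = xg) at points (xi, yi).
# Coordinates outside the grid are clamped to the hull (constant extrapolation).
bilin_at <- function(xg, yg, z, xi, yi) {
  xi <- pmin(pmax(xi, xg[1]), xg[length(xg)])
  yi <- pmin(pmax(yi, yg[1]), yg[length(yg)])
  jx <- pmin(pmax(findInterval(xi, xg), 1L), length(xg) - 1L)
  jy <- pmin(pmax(findInterval(yi, yg), 1L), length(yg) - 1L)
  if (length(xg) == 1L) jx <- rep(1L, length(xi))
  if (length(yg) == 1L) jy <- rep(1L, length(yi))
  x0 <- xg[jx]; x1 <- xg[pmin(jx + 1L, length(xg))]
  y0 <- yg[jy]; y1 <- yg[pmin(jy + 1L, length(yg))]
  fx <- ifelse(x1 > x0, (xi - x0) / (x1 - x0), 0)
  fy <- ifelse(y1 > y0, (yi - y0) / (y1 - y0), 0)
  jx1 <- pmin(jx + 1L, length(xg)); jy1 <- pmin(jy + 1L, length(yg))
  z[cbind(jy, jx)] * (1 - fy) * (1 - fx) +
    z[cbind(jy, jx1)] * (1 - fy) * fx +
    z[cbind(jy1, jx)] * fy * (1 - fx) +
    z[cbind(jy1, jx1)] * fy * fx
}

# Subpixel translation of an image by (dx, dy): output(x) = img(x + dx, y + dy),
# bilinear, edge-clamped.
translate_img <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- (1:nx) + dx
  ys <- (1:ny) + dy
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); fx <- xs - x0
  y0 <- pmin(floor(ys), ny - 1L); fy <- ys - y0
  img[y0, x0] * outer(1 - fy, 1 - fx) +
    img[y0, x0 + 1L] * outer(1 - fy, fx) +
    img[y0 + 1L, x0] * outer(fy, 1 - fx) +
    img[y0 + 1L, x0 + 1L] * outer(fy, fx)
}

# 3x3 median smoothing with edge clamping (NA entries ignored).
median3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (i in seq_len(ny)) {
    ii <- max(1L, i - 1L):min(ny, i + 1L)
    for (j in seq_len(nx)) {
      jj <- max(1L, j - 1L):min(nx, j + 1L)
      out[i, j] <- stats::median(m[ii, jj], na.rm = TRUE)
    }
  }
  out
}

# Three-point subpixel peak offset: Gaussian fit when the samples allow it,
# parabolic otherwise, 0 when the curvature is degenerate.
subpixel_peak <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    den <- log(cm) + log(cp) - 2 * log(c0)
    if (den < 0) {
      d <- (log(cm) - log(cp)) / (2 * den)
      if (is.finite(d) && abs(d) <= 1) return(d)
    }
  }
  den <- cm + cp - 2 * c0
  if (den < 0) {
    d <- (cm - cp) / (2 * den)
    if (is.finite(d) && abs(d) <= 1) return(d)
  }
  0
}

# Bilinear extraction of a w x w window whose top-left corner sits at the
# (possibly fractional) image position (x0, y0); edge-clamped.
window_at <- function(img, x0, y0, w) {
  xs <- x0 + 0:(w - 1L)
  ys <- y0 + 0:(w - 1L)
  nx <- ncol(img); ny <- nrow(img)
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  cx <- pmin(floor(xs), nx - 1L); fx <- xs - cx
  cy <- pmin(floor(ys), ny - 1L); fy <- ys - cy
  img[cy, cx] * outer(1 - fy, 1 - fx) +
    img[cy, cx + 1L] * outer(1 - fy, fx) +
    img[cy + 1L, cx] * outer(fy, 1 - fx) +
    img[cy + 1L, cx + 1L] * outer(fy, fx)
}

# Circular normalized cross-correlation peak between two equal-size windows.
# Returns NULL for a degenerate (flat) window, otherwise list(dx, dy, corr):
# displacement of `cur` relative to `ref` in px, restricted to |lag| <= max_disp.
ncc_peak <- function(ref, cur, max_disp) {
  a0 <- ref - mean(ref)
  b0 <- cur - mean(cur)
  sa <- sqrt(sum(a0^2)); sb <- sqrt(sum(b0^2))
  if (sa == 0 || sb == 0) return(NULL)
  cc <- ifft_re(Conj(stats::fft(a0)) * stats::fft(b0)) / (sa * sb)
  ny <- nrow(cc); nx <- ncol(cc)
  mdx <- min(max_disp, floor((nx - 1) / 2))
  mdy <- min(max_disp, floor((ny - 1) / 2))
  lags_x <- c(0:mdx, (-mdx):(-1))
  lags_y <- c(0:mdy, (-mdy):(-1))
  sub <- cc[(lags_y %% ny) + 1L, (lags_x %% nx) + 1L, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ly <- lags_y[pk[1]]; lx <- lags_x[pk[2]]
  c0 <- sub[pk[1], pk[2]]
  at <- function(lyy, lxx) cc[(lyy %% ny) + 1L, (lxx %% nx) + 1L]
  dx <- lx; dy <- ly
  if (abs(lx) < mdx) dx <- lx + subpixel_peak(at(ly, lx - 1L), c0, at(ly, lx + 1L))
  if (abs(ly) < mdy) dy <- ly + subpixel_peak(at(ly - 1L, lx), c0, at(ly + 1L, lx))
  list(dx = dx, dy = dy, corr = c0)
}
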