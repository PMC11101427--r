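#' Synthetic labeled fusion masks with known counts
#'
#' Builds a nuclei mask, a syncytium mask and a Syndecan-1 mask whose
#' connected-component structure realizes exactly the requested tallies, so
#' the mask-based counting step can be checked for equality (not tolerance)
#' against ground truth. Nuclei are disks on a jittered grid; each syncytium
#' is a rectangular labeled region containing exactly its member nuclei;
#' Syndecan-1-positive regions are a subset of the syncytia.
#'
#' @param n_nuclei Total number of nuclei (T).
#' @param n_syncytia Number of syncytia (S).
#' @param nuclei_per_syncytium Integer vector of length `n_syncytia`, each
#'   >= 2, summing to at most `n_nuclei`.
#' @param fraction_syndecan Fraction of the syncytia marked Syndecan-1
#'   positive (rounded to whole syncytia; ground-truth FS is the number of
#'   nuclei they contain).
#' @param seed Integer RNG seed (controls nucleus jitter only).
#' @return List with logical matrices `nuclei_mask`, `syncytium_mask`,
#'   `syndecan_mask` and the ground-truth `counts` ([fusion_counts()]).
#' @export
make_fusion_labels <- function(n_nuclei, n_syncytia = 0L,
                               nuclei_per_syncytium = integer(),
                               fraction_syndecan = 1, seed = 1L) {
  n_nuclei <- as.integer(n_nuclei)
  n_syncytia <- as.integer(n_syncytia)
  m <- as.integer(nuclei_per_syncytium)
  if (length(m) != n_syncytia)
    stop("`nuclei_per_syncytium` must have length `n_syncytia`")
  if (any(m < 2L)) stop("each syncytium needs >= 2 nuclei")
  if (sum(m) > n_nuclei)
    stop("sum of syncytial nuclei exceeds `n_nuclei`")
  if (fraction_syndecan < 0 || fraction_syndecan > 1)
    stop("`fraction_syndecan` must be in [0, 1]")
  set.seed(seed)
  s <- 14L       # grid cell size (px)
  rad <- 4L      # nucleus disk radius (px)
  n_single <- n_nuclei - sum(m)
  # block geometry per syncytium: bc x br grid cells, filled row-major
  bc <- ifelse(m > 0L, ceiling(sqrt(m)), 0L)
  br <- ifelse(bc > 0L, ceiling(m / bc), 0L)
  width_cells <- max(c(bc, ceiling(sqrt(max(n_single, 1))), 1L))
  single_rows <- if (n_single > 0L) ceiling(n_single / width_cells) else 0L
  total_rows <- sum(br + 1L) + single_rows + 1L
  ny <- (total_rows + 1L) * s
  nx <- (width_cells + 2L) * s
  nuclei <- matrix(FALSE, ny, nx)
  syncytium <- matrix(FALSE, ny, nx)
  syndecan <- matrix(FALSE, ny, nx)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ysm <- matrix(seq_len(ny), ny, nx)
  stamp_nucleus <- function(cxp, cyp) {
    sel <- (xs - cxp)^2 + (ysm - cyp)^2 <= rad^2
    nuclei[sel] <<- TRUE
  }
  cell_center <- function(row, col) {
    # cell (row, col) zero-based; 1-cell margin around the layout
    c(x = (col + 1L) * s + s / 2 + stats::runif(1, -2, 2),
      y = (row + 1L) * s + s / 2 + stats::runif(1, -2, 2))
  }
  k_synd <- round(fraction_syndecan * n_syncytia)
  fs_truth <- if (k_synd > 0L) sum(m[seq_len(k_synd)]) else 0L
  row_cursor <- 0L
  for (j in seq_len(n_syncytia)) {
    for (q in seq_len(m[j])) {
      rr <- row_cursor + (q - 1L) %/% bc[j]
      cc <- (q - 1L) %% bc[j]
      p <- cell_center(rr, cc)
      stamp_nucleus(p["x"], p["y"])
    }
    # rectangle spanning the block, inset 2 px from the cell boundary
    y0 <- (row_cursor + 1L) * s + 2L
    y1 <- (row_cursor + br[j] + 1L) * s - 2L
    x0 <- s + 2L
    x1 <- (bc[j] + 1L) * s - 2L
    syncytium[y0:y1, x0:x1] <- TRUE
    if (j <= k_synd) syndecan[y0:y1, x0:x1] <- TRUE
    row_cursor <- row_cursor + br[j] + 1L
  }
  for (q in seq_len(n_single)) {
    rr <- row_cursor + (q - 1L) %/% width_cells
    cc <- (q - 1L) %% width_cells
    p <- cell_center(rr, cc)
    stamp_nucleus(p["x"], p["y"])
  }
  list(nuclei_mask = nuclei, syncytium_mask = syncytium,
       syndecan_mask = syndecan,
       counts = fusion_counts(T = n_nuclei, F = sum(m), S = n_syncytia,
                              FS = fs_truth))
}
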