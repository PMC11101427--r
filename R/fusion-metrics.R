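#' Nuclear / syncytium tallies for fusion-efficiency statistics
#'
#' @param T Total number of nuclei in the field.
#' @param F Number of nuclei residing within syncytia.
#' @param S Number of syncytia (a syncytium being 2 or more cells sharing one
#'   membrane boundary).
#' @param FS Number of nuclei in Syndecan-1-positive regions.
#' @return Object of class `fusion_counts`.
#' @export
fusion_counts <- function(T, F = 0L, S = 0L, FS = 0L) {
  T <- as.integer(T); F <- as.integer(F); S <- as.integer(S); FS <- as.integer(FS)
  if (any(c(T, F, S, FS) < 0L)) stop("counts must be non-negative")
  if (F > T) stop("F (fused nuclei) cannot exceed T (total nuclei)")
  if (FS > T) stop("FS cannot exceed T")
  if (S > 0L && F < 2L * S)
    stop("each syncytium holds >= 2 nuclei, so F >= 2*S is required")
  structure(list(T = T, F = F, S = S, FS = FS), class = "fusion_counts")
}

#' @export
print.fusion_counts <- function(x, ...) {
  cat(sprintf("<fusion_counts> T=%d F=%d S=%d FS=%d\n", x$T, x$F, x$S, x$FS))
  invisible(x)
}

#' Derive fusion counts from labeled masks
#'
#' Connected-component counting on binary masks: `T` is the number of nucleus
#' components, `S` the number of syncytium components, `F` the number of
#' nuclei whose centroid falls inside a syncytium component, and `FS` the
#' number of nuclei whose centroid falls inside the Syndecan-1-positive mask.
#' Centroid-in-component membership makes the tally robust to partial
#' boundary overlap.
#'
#' @param nuclei_mask,syncytium_mask,syndecan_mask Binary matrices of equal
#'   shape (syncytium/syndecan masks may be NULL for none).
#' @return A [fusion_counts()].
#' @export
derive_counts <- function(nuclei_mask, syncytium_mask = NULL,
                          syndecan_mask = NULL) {
  nuclei_mask <- nuclei_mask > 0
  if (is.null(syncytium_mask)) syncytium_mask <- array(FALSE, dim(nuclei_mask))
  if (is.null(syndecan_mask)) syndecan_mask <- array(FALSE, dim(nuclei_mask))
  if (!all(dim(syncytium_mask) == dim(nuclei_mask)) ||
      !all(dim(syndecan_mask) == dim(nuclei_mask)))
    stop("masks must share shape")
  lab_n <- EBImage::bwlabel(nuclei_mask * 1)
  n_T <- max(lab_n)
  if (n_T == 0L) return(fusion_counts(0L, 0L, 0L, 0L))
  idx <- which(lab_n > 0, arr.ind = TRUE)
  cx <- round(tapply(idx[, 2], lab_n[lab_n > 0], mean))
  cy <- round(tapply(idx[, 1], lab_n[lab_n > 0], mean))
  lab_s <- EBImage::bwlabel((syncytium_mask > 0) * 1)
  in_syn <- (lab_s > 0)[cbind(cy, cx)]
  in_fs <- (syndecan_mask > 0)[cbind(cy, cx)]
  fusion_counts(T = n_T, F = sum(in_syn), S = max(lab_s), FS = sum(in_fs))
}

#' Fusion efficiency from E-cadherin junctional analysis
#'
#' `100 * (F - S + 1) / T` when at least one syncytium exists. The `+1` term
#' makes a single fully fused sheet (F = T, S = 1) score exactly 100%; for a
#' field with no syncytia at all (S = 0) the formula is short-circuited to 0
#' rather than returning the spurious `1/T`.
#'
#' @param c A [fusion_counts()] with `T > 0`.
#' @return Fusion efficiency in percent.
#' @export
efficiency_ecadherin <- function(c) {
  if (c$T <= 0L) stop("T must be positive")
  if (c$S == 0L) return(0)
  100 * (c$F - c$S + 1) / c$T
}

#' Fusion efficiency from Syndecan-1 expression
#'
#' `100 * FS / T`: the fraction of nuclei residing in Syndecan-1-positive
#' (fused) regions.
#'
#' @param c A [fusion_counts()] with `T > 0`.
#' @return Fusion efficiency in percent.
#' @export
efficiency_syndecan <- function(c) {
  if (c$T <= 0L) stop("T must be positive")
  100 * c$FS / c$T
}

#' Nuclear density over a fixed viewfield area
#'
#' @param T Nucleus count.
#' @param area Viewfield area in mm^2 (default 0.34, the standard analysis
#'   viewfield).
#' @return Nuclei per mm^2.
#' @export
nuclear_density <- function(T, area = 0.34) {
  if (area <= 0) stop("`area` must be positive")
  T / area
}

#' Volume-normalized fusion marker level for a spheroid
#'
#' Total integrated marker intensity (Syndecan-1 or beta-hCG) across all
#' optical sections divided by the spheroid volume estimated from per-slice
#' areas times the slice spacing: `Fusion (AU) = total integrated density /
#' total spheroid volume`.
#'
#' @param intensity Per-slice integrated intensities (AU).
#' @param area Per-slice spheroid cross-section areas (um^2).
#' @param spacing Optical slice spacing in um (default 10).
#' @return Fusion level in AU per um^3.
#' @export
spheroid_fusion_au <- function(intensity, area, spacing = 10) {
  if (length(intensity) != length(area)) stop("one area per slice required")
  if (length(intensity) < 1L) stop("at least one slice required")
  if (spacing <= 0) stop("`spacing` must be positive")
  vol <- sum(area) * spacing
  if (vol <= 0) stop("total spheroid volume must be positive")
  sum(intensity) / vol
}

#' Normalize fusion values to a batch control
#'
#' Fold-change normalization used to compare across passages: each value is
#' divided by the mean of its batch's control values (passage number affects
#' baseline fusion efficiency, so absolute efficiencies are not comparable
#' across batches).
#'
#' @param values Numeric vector of treated-condition values.
#' @param control_values Numeric vector of the batch's control values
#'   (mean > 0).
#' @return Fold values (dimensionless).
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}

#' Read / write fusion count tables
#'
#' CSV interchange for count tables: columns `sample_id, condition, T, F, S,
#' FS` (extra columns preserved).
#'
#' @param path CSV path.
#' @return Data frame of counts.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("T", "F", "S", "FS")
  if (!all(need %in% names(df)))
    stop("counts CSV must have columns T, F, S, FS")
  df
}

#' @rdname read_counts_csv
#' @param df Data frame with at least columns `T, F, S, FS`.
#' @export
write_counts_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
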