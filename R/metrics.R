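#' Rubber-band baseline of a spectral segment
#'
#' The baseline is the lower convex hull of the `(axis, value)` points,
#' linearly interpolated between hull vertices and anchored at both segment
#' endpoints. Subtracting it yields a nonnegative corrected segment that is
#' exactly zero at the hull vertices.
#'
#' @param values Numeric segment values.
#' @param axis Strictly increasing wavenumbers for the segment.
#' @return Numeric baseline, same length as `values`.
#' @export
rubberband_baseline <- function(values, axis) {
  if (length(values) < 2) abort("need at least 2 points for a baseline")
  if (length(values) != length(axis)) abort("values/axis length mismatch")
  if (any(diff(axis) <= 0)) abort("axis must be strictly increasing")
  .rubberband_cpp(as.numeric(axis), as.numeric(values))
}

#' Spectral metrics of one region of a spectrum
#'
#' The segment of the spectrum falling in `[lo, hi]` is baseline-corrected
#' with the rubber band, then three metrics are computed on the corrected
#' values: the maximum, the center of gravity `sum(v * A) / sum(A)` (cm^-1)
#' and the trapezoidal integral over the region. A segment with zero
#' corrected mass gets the region midpoint as its (degenerate) center of
#' gravity so feature rows stay finite.
#'
#' @param spectrum Numeric spectrum over `axis`.
#' @param axis Ascending wavenumber axis.
#' @param lo,hi Region bounds (closed interval).
#' @return Named numeric vector `c(max =, cog =, area =)`.
#' @export
region_metrics <- function(spectrum, axis, lo, hi) {
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0) abort("region lies outside the axis range")
  if (length(idx) < 3) abort("region covers fewer than 3 grid points")
  m <- .region_metrics_cpp(matrix(spectrum[idx], 1), axis[idx])
  cog <- if (is.na(m[1, 2])) (lo + hi) / 2 else m[1, 2]
  c(max = m[1, 1], cog = cog, area = m[1, 3])
}

# region -> axis index list, validated against the table's preconditions
region_indices <- function(axis, region_table) {
  lapply(seq_len(nrow(region_table)), function(i) {
    idx <- which(axis >= region_table$lo_cm1[i] & axis <= region_table$hi_cm1[i])
    if (length(idx) < 3)
      abort(sprintf("region '%s' covers %d grid points (need >= 3)",
                    region_table$name[i], length(idx)))
    idx
  })
}

#' Build the normalized pixel feature table of a cube
#'
#' For every tissue pixel, each region of the table is baseline-corrected
#' locally and summarized by its maximum, center of gravity and integrated
#' area; all three are then divided by the corresponding Amide I metric,
#' removing multiplicative section-thickness effects. The Amide I region's
#' own (identically 1) columns are dropped, so an `n`-region table yields
#' `3 * (n - 1)` feature columns — 123 with the default 42-region table.
#' Pixels whose Amide I area is not positive cannot be normalized; they are
#' excluded and their count reported via the `n_invalid` attribute.
#'
#' @param cube A [hyper_cube()].
#' @param labels Optional integer label matrix ([class_codes()]); when
#'   `NULL` all tissue pixels are included with label `NA`.
#' @param region_table A `region_table` (default [default_region_table()]).
#' @param normalize_cog Divide centers of gravity by the Amide I center of
#'   gravity (default `TRUE`); set `FALSE` to keep band positions in cm^-1.
#' @return Tibble with columns `mouse_id`, `row`, `col`, `label`, then the
#'   normalized feature columns `<region>_<metric>`.
#' @export
build_feature_table <- function(cube, labels = NULL,
                                region_table = default_region_table(),
                                normalize_cog = TRUE) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  px <- which(cube$tissue_mask)
  rc <- arrayInd(px, d[1:2])
  X <- cube_spectra(cube, px)
  idxs <- region_indices(cube$axis, region_table)
  a1 <- which(region_table$is_amide1)
  n_regions <- nrow(region_table)

  mets <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    idx <- idxs[[i]]
    m <- .region_metrics_cpp(X[, idx, drop = FALSE], cube$axis[idx])
    mid <- (region_table$lo_cm1[i] + region_table$hi_cm1[i]) / 2
    m[is.na(m[, 2]), 2] <- mid
    mets[[i]] <- m
  }
  ref <- mets[[a1]]
  valid <- ref[, 3] > 0
  n_invalid <- sum(!valid)
  if (!any(valid)) abort("every pixel has nonpositive Amide I area")
  if (n_invalid > 0)
    warn(sprintf("%d pixel(s) with nonpositive Amide I area excluded", n_invalid))

  keep <- which(valid)
  feats <- vector("list", n_regions - 1L)
  nms <- character(0)
  j <- 0L
  for (i in seq_len(n_regions)) {
    if (i == a1) next
    j <- j + 1L
    m <- mets[[i]][keep, , drop = FALSE]
    r <- ref[keep, , drop = FALSE]
    cogv <- if (normalize_cog) m[, 2] / r[, 2] else m[, 2]
    feats[[j]] <- cbind(m[, 1] / r[, 1], cogv, m[, 3] / r[, 3])
    nms <- c(nms, paste0(region_table$name[i], "_", c("max", "cog", "area")))
  }
  Fm <- do.call(cbind, feats)
  colnames(Fm) <- nms

  lab <- if (is.null(labels)) rep(NA_character_, length(px)) else {
    code <- labels[px]
    names(SH_CLASSES)[match(code, SH_CLASSES)]
  }
  out <- tibble::tibble(
    mouse_id = cube$meta$mouse_id,
    row = rc[keep, 1], col = rc[keep, 2],
    label = lab[keep]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(Fm))
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Retain interior tissue pixels (edge exclusion)
#'
#' Erodes the tissue mask by one pixel with 8-connectivity: a pixel is
#' retained iff it and all 8 neighbours are tissue. Edge pixels are excluded
#' from model training and validation (prediction maps may still cover
#' them), guarding against border artifacts of the uncorrected transflection
#' geometry.
#'
#' @param labels Integer label matrix (unused for the geometry but kept in
#'   the signature so the retained set can be intersected with labels).
#' @param tissue_mask Logical matrix.
#' @return Logical matrix: `TRUE` for retained interior tissue pixels.
#' @export
exclude_edge_pixels <- function(labels = NULL, tissue_mask) {
  H <- nrow(tissue_mask); W <- ncol(tissue_mask)
  m <- matrix(FALSE, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- tissue_mask
  keep <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    keep <- keep & m[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  }
  keep
}
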