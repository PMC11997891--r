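#' Hyperspectral absorbance cube
#'
#' The raster currency of the pipeline: an `H x W x B` absorbance array with
#' a strictly monotone wavenumber axis (stored ascending), a logical tissue
#' mask and per-measurement metadata. A descending axis is accepted and
#' re-sorted, with the band dimension permuted consistently.
#'
#' @param data Numeric `H x W x B` array of absorbance values.
#' @param axis Numeric vector of `B` wavenumbers (cm^-1), strictly monotone.
#' @param tissue_mask Logical `H x W` matrix; `TRUE` pixels participate in the
#'   analysis. Defaults to all `TRUE`.
#' @param mouse_id,genotype Optional metadata strings.
#'
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, axis, tissue_mask = NULL, mouse_id = NA_character_,
                       genotype = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be an H x W x B array")
  axis <- as.numeric(axis)
  if (length(axis) != dim(data)[3])
    abort(sprintf("axis length (%d) does not match band count (%d)",
                  length(axis), dim(data)[3]))
  d <- diff(axis)
  if (any(d == 0)) abort("wavenumber axis contains duplicate values")
  if (all(d < 0)) { # stored ascending internally
    axis <- rev(axis)
    data <- data[, , rev(seq_along(axis)), drop = FALSE]
  } else if (any(d < 0)) {
    abort("wavenumber axis must be strictly monotone")
  }
  if (anyNA(data)) abort("cube contains NA absorbance values")
  if (is.null(tissue_mask))
    tissue_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  if (!identical(dim(tissue_mask), dim(data)[1:2]))
    abort("tissue_mask shape does not match cube")
  structure(
    list(data = data, axis = axis, tissue_mask = tissue_mask,
         meta = list(mouse_id = mouse_id, genotype = genotype)),
    class = "hyper_cube"
  )
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.0f-%.0f cm-1)\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis)))
  cat(sprintf("  tissue pixels: %d / %d; mouse_id: %s; genotype: %s\n",
              sum(x$tissue_mask), d[1] * d[2],
              x$meta$mouse_id, x$meta$genotype))
  invisible(x)
}

# pixel spectra as an n x B matrix for masked pixels (row-major pixel order)
cube_spectra <- function(cube, which_pixels = NULL) {
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  if (is.null(which_pixels)) which_pixels <- which(cube$tissue_mask)
  X[which_pixels, , drop = FALSE]
}

# scalar multiplication preserves class (used by scale-invariance checks)
#' @export
`*.hyper_cube` <- function(e1, e2) {
  if (inherits(e1, "hyper_cube")) { cube <- e1; a <- e2 } else { cube <- e2; a <- e1 }
  cube$data <- cube$data * a
  cube
}
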