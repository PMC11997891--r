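#' Write / read a hyperspectral cube as an ENVI header + binary pair
#'
#' The cube is stored in the standard ENVI layout: a text header
#' (`<path>.hdr`) carrying dimensions, interleave, the wavelength list and
#' the `mouse id` / `genotype` metadata, plus a raw binary file
#' (`<path>.dat`). Writing uses 64-bit floats (ENVI data type 5) and BSQ
#' interleave, so a write -> read round trip reproduces the data exactly.
#' The tissue mask is stored alongside as an 8-bit PNG (`<path>_mask.png`).
#' Readers accept BSQ, BIL and BIP interleaves and data types 4 (float32)
#' and 5 (float64); a descending wavelength axis is re-sorted ascending with
#' the band order permuted consistently.
#'
#' @param cube A [hyper_cube()].
#' @param path Base path (without extension) or a `.hdr` path.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` returns a
#'   [hyper_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  path <- sub("\\.(hdr|dat)$", "", path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {spectrohist hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    sprintf("byte order = %d", if (.Platform$endian == "little") 0L else 1L),
    "wavelength units = Wavenumber",
    sprintf("mouse id = %s", cube$meta$mouse_id),
    sprintf("genotype = %s", cube$meta$genotype),
    sprintf("wavelength = {%s}",
            paste(format(cube$axis, digits = 15, trim = TRUE, scientific = FALSE),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ, ENVI pixel order: band-major, then line (row), then sample (col)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), con, size = 8)
  png::writePNG(matrix(as.numeric(cube$tissue_mask), d[1], d[2]),
                target = paste0(path, "_mask.png"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines[-1], collapse = "\n")
  # join multi-line { ... } values
  fields <- list()
  pos <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1]]
  starts <- pos
  lens <- attr(pos, "match.length")
  for (i in seq_along(starts)) {
    chunk <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*", "", chunk))
    val <- trimws(sub("^[^=]*=", "", chunk))
    fields[[tolower(key)]] <- val
  }
  fields
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  base <- sub("\\.hdr$", "", hdr_path)
  if (!file.exists(hdr_path)) abort(sprintf("header not found: %s", hdr_path))
  f <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss)) abort(sprintf("ENVI header missing field(s): %s",
                                  paste(miss, collapse = ", ")))
  if (is.null(f[["wavelength"]]))
    abort("ENVI header missing `wavelength` list")
  W <- as.integer(f$samples); H <- as.integer(f$lines); B <- as.integer(f$bands)
  dtype <- as.integer(f[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 abort(sprintf("unsupported ENVI data type %d", dtype)))
  axis <- as.numeric(strsplit(gsub("[{}]", "", f$wavelength), ",")[[1]])
  if (length(axis) != B)
    abort(sprintf("wavelength list length (%d) does not match bands (%d)",
                  length(axis), B))
  if (anyDuplicated(axis))
    abort("wavelength axis contains duplicates; cannot sort strictly")
  dat_path <- paste0(base, ".dat")
  if (!file.exists(dat_path)) {
    alt <- sub("\\.dat$", "", dat_path)
    if (file.exists(alt)) dat_path <- alt
    else abort(sprintf("binary file not found: %s", dat_path))
  }
  endian <- if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) == 1)
    "big" else "little"
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = H * W * B, size = size, endian = endian)
  if (length(raw) != H * W * B)
    abort("binary payload shorter than samples*lines*bands")
  interleave <- tolower(f$interleave)
  cube <- switch(interleave,
    bsq = aperm(array(raw, c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(raw, c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(raw, c(B, W, H)), c(3, 2, 1)),
    abort(sprintf("unknown interleave '%s'", interleave))
  )
  mask_path <- paste0(base, "_mask.png")
  mask <- if (file.exists(mask_path)) read_mask_png(mask_path) else NULL
  hyper_cube(cube, axis, tissue_mask = mask,
             mouse_id = if (is.null(f[["mouse id"]])) NA_character_ else f[["mouse id"]],
             genotype = if (is.null(f[["genotype"]])) NA_character_ else f[["genotype"]])
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write / read a label mask as an 8-bit PNG
#'
#' Labels use the fixed code map (see [class_codes()]); codes are stored in
#' the 8-bit gray channel directly (value = code / 255).
#'
#' @param labels Integer matrix of class codes.
#' @param path PNG path.
#' @return `read_label_mask()` returns an integer matrix.
#' @export
write_label_mask <- function(labels, path) {
  png::writePNG(matrix(as.numeric(labels) / 255, nrow(labels), ncol(labels)),
                target = path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read a spectral region table
#'
#' A region table is a TSV with columns `name`, `lo_cm1`, `hi_cm1` and an
#' optional logical `is_amide1` column flagging exactly one row: the Amide I
#' band used for normalization. Regions may overlap (the DNA/RNA 1180-980
#' region contains the 1180-1140 carbohydrate region).
#'
#' @param path TSV path.
#' @return A tibble of class `region_table`, ordered as in the file.
#' @export
read_region_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_region_table(tb)
}

#' @rdname read_region_table
#' @param regions Data frame with `name`, `lo_cm1`, `hi_cm1`, `is_amide1`.
#' @export
as_region_table <- function(regions) {
  tb <- tibble::as_tibble(regions)
  if (!all(c("name", "lo_cm1", "hi_cm1") %in% names(tb)))
    abort("region table needs columns name, lo_cm1, hi_cm1")
  if (!"is_amide1" %in% names(tb))
    tb$is_amide1 <- grepl("amide_?I$", tb$name, ignore.case = TRUE)
  tb$is_amide1 <- as.logical(tb$is_amide1)
  if (any(tb$lo_cm1 >= tb$hi_cm1))
    abort("every region must satisfy lo < hi")
  n_a1 <- sum(tb$is_amide1)
  if (n_a1 != 1L)
    abort(sprintf("region table must flag exactly one Amide I row (found %d)", n_a1))
  if (anyDuplicated(tb$name)) abort("duplicate region names")
  class(tb) <- c("region_table", class(tb))
  tb
}

#' Default 42-region table
#'
#' A surrogate for the region set driving baseline correction and metric
#' extraction: the named biology-bearing regions (Amide A+B 3600-3000,
#' Amide I 1762-1585 as normalization region, Amide II 1585-1473, collagen
#' 1346-1325, carbohydrate 1180-1140, DNA/RNA 1180-980, lipid CH stretch
#' 3000-2800) plus contiguous tiling intervals over the 1473-900 fingerprint
#' and 3000-2800 CH regions, totalling 42 rows so the feature arithmetic
#' (3 metrics x 41 normalized regions = 123) matches the published pipeline.
#' Fully replaceable via [read_region_table()].
#'
#' @return A `region_table` tibble of 42 rows.
#' @export
default_region_table <- function() {
  named <- tibble::tibble(
    name = c("amide_AB", "amide_I", "amide_II", "collagen_1337",
             "carb_1160", "dna_rna", "lipid_CH"),
    lo_cm1 = c(3000, 1585, 1473, 1325, 1140, 980, 2800),
    hi_cm1 = c(3600, 1762, 1585, 1346, 1180, 1180, 3000),
    is_amide1 = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  fp_edges <- seq(900, 1473, length.out = 31)   # 30 fingerprint tiles
  ch_edges <- seq(2800, 3000, length.out = 6)   #  5 CH-stretch tiles
  tiles <- tibble::tibble(
    name = c(sprintf("fp_%04.0f", fp_edges[-31]), sprintf("ch_%04.0f", ch_edges[-6])),
    lo_cm1 = c(fp_edges[-31], ch_edges[-6]),
    hi_cm1 = c(fp_edges[-1], ch_edges[-1]),
    is_amide1 = FALSE
  )
  as_region_table(rbind(named, tiles))
}

#' @rdname read_region_table
#' @param regions A `region_table`.
#' @export
write_region_table <- function(regions, path) {
  readr::write_tsv(regions, path, progress = FALSE)
  invisible(path)
}

#' Write / read a pixel feature table as TSV
#'
#' Columns: `mouse_id`, `row`, `col`, `label`, then the normalized metric
#' columns named `<region>_<metric>` with metric one of `max`, `cog`, `area`.
#' Values round-trip at full double precision (>= 12 significant digits) and
#' column order is preserved.
#'
#' @param table Feature table (tibble).
#' @param path TSV path.
#' @return `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table))) abort("duplicate feature column names")
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  id_cols <- c("mouse_id", "row", "col", "label")
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (anyDuplicated(hdr)) abort("duplicate feature column names")
  tb <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          mouse_id = readr::col_character(),
                          row = readr::col_integer(),
                          col = readr::col_integer(),
                          label = readr::col_character(),
                          .default = readr::col_double()
                        )))
  feat <- setdiff(names(tb), id_cols)
  for (cn in feat) {
    bad <- which(!is.finite(tb[[cn]]))
    if (length(bad))
      abort(sprintf("non-numeric value in feature column '%s' at row %d",
                    cn, bad[1]))
  }
  tb
}
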