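test_that("rubber-band baseline matches the worked three-point example", {
  base <- rubberband_baseline(c(0, 3, 1), c(0, 1, 2))
  expect_equal(base, c(0, 0.5, 1))
  expect_equal(c(0, 3, 1) - base, c(0, 2.5, 0))
})

test_that("a linear segment is its own baseline", {
  axis <- seq(1000, 1100, 10)
  vals <- 0.3 + 0.002 * (axis - 1000)
  expect_equal(rubberband_baseline(vals, axis), vals)
})

test_that("a peak with equal endpoints gets a constant baseline", {
  axis <- seq(-5, 5, 0.5)
  vals <- 0.2 + exp(-axis^2)
  base <- rubberband_baseline(vals, axis)
  expect_equal(base, rep(vals[1], length(axis)), tolerance = 1e-12)
})

test_that("rubber band equals the brute-force lower hull on random segments", {
  set.seed(77)
  for (rep in 1:200) {
    m <- sample(3:25, 1)
    axis <- sort(runif(m, 900, 1800))
    axis <- axis + seq_len(m) * 1e-6   # guard strict monotonicity
    vals <- runif(m)
    got <- rubberband_baseline(vals, axis)
    want <- oracle_rubberband(axis, vals)
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(all(vals - got >= -1e-12))
  }
  expect_error(rubberband_baseline(1, 1000), "2 points")
})

test_that("region metrics match hand arithmetic on a triangle peak", {
  # spectrum whose corrected segment is [0, 2.5, 0] on axis [0, 1, 2]:
  # use values [0, 3, 1] so the hull removes the tilt
  m <- region_metrics(c(0, 3, 1), c(0, 1, 2), 0, 2)
  expect_equal(unname(m["max"]), 2.5)
  expect_equal(unname(m["cog"]), 1.0)
  expect_equal(unname(m["area"]), 2.5)
})

test_that("zero corrected mass falls back to the region midpoint", {
  axis <- seq(1000, 1100, 10)
  vals <- 0.2 + 0.001 * (axis - 1000)   # exactly linear -> zero corrected
  m <- region_metrics(vals, axis, 1000, 1100)
  expect_equal(unname(m["max"]), 0)
  expect_equal(unname(m["area"]), 0)
  expect_equal(unname(m["cog"]), 1050)
})

test_that("metrics are homogeneous in the spectrum scale except cog", {
  set.seed(8)
  axis <- seq(1000, 1200, 4)
  vals <- runif(length(axis))
  m1 <- region_metrics(vals, axis, 1000, 1200)
  m2 <- region_metrics(2 * vals, axis, 1000, 1200)
  expect_equal(unname(m2["max"]), 2 * unname(m1["max"]))
  expect_equal(unname(m2["area"]), 2 * unname(m1["area"]))
  expect_equal(unname(m2["cog"]), unname(m1["cog"]))
  expect_error(region_metrics(vals, axis, 2000, 2100), "outside")
})

test_that("cog stays inside its region for every pixel and region", {
  ph <- make_phantom(feature_params(), seed = 12)
  rt <- default_region_table()
  X <- ph$cube$data
  px <- which(ph$cube$tissue_mask)[1:20]
  d <- dim(X)
  for (i in seq_len(nrow(rt))) {
    for (p in px) {
      rc <- arrayInd(p, d[1:2])
      m <- region_metrics(X[rc[1], rc[2], ], ph$cube$axis,
                          rt$lo_cm1[i], rt$hi_cm1[i])
      expect_gte(m[["cog"]], rt$lo_cm1[i])
      expect_lte(m[["cog"]], rt$hi_cm1[i])
    }
  }
})

test_that("feature count follows the 3(n-1) law", {
  ph <- make_phantom(feature_params(), seed = 13)
  feat_cols <- function(tb) setdiff(names(tb), c("mouse_id", "row", "col", "label"))
  ft_default <- build_feature_table(ph$cube, ph$labels)
  expect_length(feat_cols(ft_default), 123)

  two <- as_region_table(data.frame(
    name = c("amide_I", "amide_II"),
    lo_cm1 = c(1585, 1473), hi_cm1 = c(1762, 1585),
    is_amide1 = c(TRUE, FALSE)))
  ft2 <- build_feature_table(ph$cube, ph$labels, two)
  expect_length(feat_cols(ft2), 3)

  for (n in c(4, 7)) {
    edges <- seq(1000, 1400, length.out = n)
    rt <- as_region_table(data.frame(
      name = c("amide_I", sprintf("r%02d", seq_len(n - 1))),
      lo_cm1 = c(1585, edges[-n]), hi_cm1 = c(1762, edges[-1]),
      is_amide1 = c(TRUE, rep(FALSE, n - 1))))
    expect_length(feat_cols(build_feature_table(ph$cube, ph$labels, rt)),
                  3 * (n - 1))
  }
})

test_that("features are invariant under uniform spectral scaling", {
  p <- feature_params(noise_sigma_white = 0, noise_sigma_corr = 0)
  ph <- make_phantom(p, seed = 14)
  ft1 <- build_feature_table(ph$cube, ph$labels)
  ft2 <- build_feature_table(ph$cube * 2, ph$labels)
  feats <- setdiff(names(ft1), c("mouse_id", "row", "col", "label"))
  expect_equal(as.matrix(ft2[, feats]), as.matrix(ft1[, feats]),
               tolerance = 1e-6)
})

test_that("scale invariance survives the full MNF + metrics path", {
  p <- small_params(noise_sigma_white = 0, noise_sigma_corr = 0)
  ph <- make_phantom(p, seed = 15)
  rt <- as_region_table(data.frame(
    name = c("amide_I", "amide_II", "fp1", "fp2"),
    lo_cm1 = c(1585, 1473, 1000, 1100),
    hi_cm1 = c(1762, 1585, 1100, 1200),
    is_amide1 = c(TRUE, FALSE, FALSE, FALSE)))
  f1 <- build_feature_table(mnf_denoise(ph$cube, k = 10), ph$labels, rt)
  f2 <- build_feature_table(mnf_denoise(ph$cube * 3, k = 10), ph$labels, rt)
  feats <- setdiff(names(f1), c("mouse_id", "row", "col", "label"))
  expect_equal(as.matrix(f2[, feats]), as.matrix(f1[, feats]),
               tolerance = 1e-6)
})

test_that("identically scaled pixels produce identical feature rows", {
  ph <- make_phantom(feature_params(), seed = 16)
  cube <- ph$cube
  px <- which(cube$tissue_mask)
  d <- dim(cube$data)
  rcA <- arrayInd(px[1], d[1:2]); rcB <- arrayInd(px[2], d[1:2])
  cube$data[rcB[1], rcB[2], ] <- 2 * cube$data[rcA[1], rcA[2], ]
  ft <- build_feature_table(cube, ph$labels)
  feats <- setdiff(names(ft), c("mouse_id", "row", "col", "label"))
  rowA <- ft[ft$row == rcA[1] & ft$col == rcA[2], feats]
  rowB <- ft[ft$row == rcB[1] & ft$col == rcB[2], feats]
  expect_equal(as.numeric(rowA), as.numeric(rowB), tolerance = 1e-9)
})

test_that("pixels without Amide I mass are excluded with a count", {
  ph <- make_phantom(feature_params(), seed = 17)
  cube <- ph$cube
  px <- which(cube$tissue_mask)
  rc <- arrayInd(px[1], dim(cube$data)[1:2])
  cube$data[rc[1], rc[2], ] <- 0.5   # flat -> zero corrected everywhere
  expect_warning(ft <- build_feature_table(cube, ph$labels), "1 pixel")
  expect_equal(attr(ft, "n_invalid"), 1)
  expect_equal(nrow(ft), length(px) - 1)

  flat <- cube
  flat$data[] <- 0.5
  expect_error(suppressWarnings(build_feature_table(flat, ph$labels)),
               "every pixel")
})

test_that("edge exclusion equals the brute-force interior", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(sum(exclude_edge_pixels(tissue_mask = full)), 64)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(sum(exclude_edge_pixels(tissue_mask = single)), 0)

  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(runif(100) > 0.3, 10, 10)
    expect_identical(exclude_edge_pixels(tissue_mask = m), oracle_interior(m))
  }
  holed <- matrix(TRUE, 10, 10); holed[5, 5] <- FALSE
  expect_identical(exclude_edge_pixels(tissue_mask = holed),
                   oracle_interior(holed))
})
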