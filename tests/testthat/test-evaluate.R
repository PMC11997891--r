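test_that("LOMO folds partition the cohort", {
  folds <- lomo_folds(sprintf("m%02d", 1:19))
  expect_equal(nrow(folds), 19)
  expect_setequal(folds$test_mouse, sprintf("m%02d", 1:19))
  for (i in seq_len(nrow(folds)))
    expect_false(folds$test_mouse[i] %in% folds$train_mice[[i]])

  two <- lomo_folds(c("a", "b"))
  expect_equal(nrow(two), 2)
  expect_equal(lengths(two$train_mice), c(1L, 1L))

  expect_error(lomo_folds(c("a", "a")), "duplicate")
  expect_error(lomo_folds("a"), "at least 2")
})

test_that("confusion matrices count correctly", {
  perfect <- pixel_confusion(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(diag(perfect$counts)), c(2L, 1L))

  cm <- pixel_confusion(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(cm$accuracy, 2 / 3)
  expect_equal(unname(cm$tpr["A"]), 1 / 2)
  expect_equal(unname(cm$tpr["B"]), 1)
  expect_equal(unname(rowSums(cm$counts)), c(2L, 1L))

  wrong <- pixel_confusion(c("A", "B"), c("B", "A"))
  expect_equal(wrong$accuracy, 0)

  expect_error(pixel_confusion(c("A", "C"), c("A", "A"), classes = c("A", "B")),
               "outside")
  expect_error(pixel_confusion(c("A", "B"), c("A")), "equal length")

  td <- tidy(cm)
  expect_equal(sum(td$n), 3)
  expect_equal(glance(cm)$accuracy, 2 / 3)
})

test_that("majority filter obeys its contracts", {
  uni <- matrix(2L, 8, 8)
  expect_identical(majority_filter(uni, 5), uni)

  iso <- matrix(1L, 7, 7); iso[4, 4] <- 2L
  expect_equal(majority_filter(iso, 5)[4, 4], 1L)

  bg <- matrix(0L, 5, 5); bg[3, 3] <- 4L
  out <- majority_filter(bg, 5)
  expect_identical(out, bg)   # background never votes, lone pixel keeps label

  expect_error(majority_filter(uni, 4), "odd")
})

test_that("majority filter equals the brute-force windowed mode", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
    expect_identical(majority_filter(m, 5), oracle_majority(m, 5))
  }
})

test_that("majority filter preserves background and never invents classes", {
  set.seed(32)
  m <- matrix(sample(c(0L, 1L, 2L, 3L), 400, replace = TRUE,
                     prob = c(0.3, 0.4, 0.2, 0.1)), 20, 20)
  out <- majority_filter(m, 5)
  expect_identical(out == 0L, m == 0L)
  expect_true(all(out %in% unique(as.vector(m))))
})

test_that("tissue ROC reproduces known AUCs", {
  perfect <- tissue_roc(tibble::tibble(
    mouse_id = letters[1:5], count = c(0, 1, 2, 50, 60),
    truth = c("healthy", "healthy", "healthy", "pathological", "pathological")))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)
  expect_equal(perfect$chosen_threshold, 2)

  tied <- tissue_roc(tibble::tibble(
    mouse_id = letters[1:4], count = rep(7, 4),
    truth = c("healthy", "healthy", "pathological", "pathological")))
  expect_equal(tied$auc, 0.5)

  mixed <- tissue_roc(tibble::tibble(
    mouse_id = letters[1:4], count = c(3, 8, 5, 9),
    truth = c("healthy", "healthy", "pathological", "pathological")))
  expect_equal(mixed$auc, 0.75)

  expect_error(tissue_roc(tibble::tibble(
    mouse_id = "a", count = 1, truth = "healthy")), "at least one")
})

test_that("trapezoid AUC equals Mann-Whitney with half ties by brute force", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    n_h <- sample(1:(n - 1), 1)
    truth <- c(rep("healthy", n_h), rep("pathological", n - n_h))
    counts <- sample(0:4, n, replace = TRUE)  # many ties by construction
    roc <- tissue_roc(tibble::tibble(
      mouse_id = as.character(seq_len(n)), count = counts, truth = truth))
    expect_equal(roc$auc, oracle_mw_auc(counts, truth), tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
  }
})

test_that("tissue ROC agrees with the rank-based Mann-Whitney statistic", {
  set.seed(42)
  counts <- c(rpois(6, 20), rpois(8, 60))
  truth <- rep(c("healthy", "pathological"), c(6, 8))
  roc <- tissue_roc(tibble::tibble(mouse_id = as.character(1:14),
                                   count = counts, truth = truth))
  w <- stats::wilcox.test(counts[truth == "pathological"],
                          counts[truth == "healthy"], exact = FALSE)
  expect_equal(roc$auc, unname(w$statistic) / (6 * 8), tolerance = 1e-12)
})

test_that("the AUC standard error follows Hanley-McNeil", {
  expect_equal(auc_se(1, 5, 14), 0)
  expect_equal(auc_se(0.5, 10, 10), sqrt(0.0175), tolerance = 1e-12)
  expect_equal(auc_se(0.5, 3, 7), auc_se(0.5, 7, 3))
  expect_error(auc_se(1.2, 5, 5), "0, 1")
  expect_error(auc_se(0.5, 0, 5), ">= 1")
})

test_that("a small noise-free separable cohort evaluates to AUC 1", {
  p <- small_params(noise_sigma_white = 0.002, noise_sigma_corr = 0,
                    mouse_effect_sigma = 0.01)
  co <- make_cohort(n_mice = 4, genotype_mix = c(control = 2, KPC = 2),
                    params = p, seed = 5)
  # regions widened to keep >= 3 grid points at this coarse axis spacing
  rt <- as_region_table(data.frame(
    name = c("amide_I", "amide_II", "dna_rna", "collagen", "carb"),
    lo_cm1 = c(1585, 1473, 980, 1290, 1130),
    hi_cm1 = c(1762, 1585, 1180, 1360, 1180),
    is_amide1 = c(TRUE, rep(FALSE, 4))))
  ev <- run_full_evaluation(co, k = 15, region_table = rt)
  expect_s3_class(ev$confusion_detailed, "sh_confusion")
  expect_equal(dim(ev$confusion_detailed$counts), c(7, 7))
  expect_equal(dim(ev$confusion_rapid$counts), c(3, 3))
  expect_s3_class(ev$roc, "sh_roc")
  expect_equal(ev$roc$auc, 1)
  expect_equal(nrow(ev$per_mouse), 4)
  expect_true(all(!is.na(ev$per_mouse$count)))

  g <- glance(ev)
  expect_equal(g$n_mice, 4)
  expect_equal(g$tissue_auc, 1)
})

test_that("evaluation is reproducible under fixed seeds", {
  p <- small_params(noise_sigma_white = 0.002, noise_sigma_corr = 0)
  co <- make_cohort(n_mice = 4, genotype_mix = c(control = 2, KPC = 2),
                    params = p, seed = 5)
  rt <- as_region_table(data.frame(
    name = c("amide_I", "amide_II", "dna_rna"),
    lo_cm1 = c(1585, 1473, 980), hi_cm1 = c(1762, 1585, 1180),
    is_amide1 = c(TRUE, FALSE, FALSE)))
  e1 <- run_full_evaluation(co, k = 10, region_table = rt)
  e2 <- run_full_evaluation(co, k = 10, region_table = rt)
  expect_identical(e1$confusion_detailed$counts, e2$confusion_detailed$counts)
  expect_identical(e1$per_mouse, e2$per_mouse)
})
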