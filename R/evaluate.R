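#' Leave-one-mouse-out folds
#'
#' One fold per mouse: that mouse's pixels form the test set, all other
#' mice form the training set, so every fold measures generalization to an
#' unseen animal. A 19-mouse cohort yields 19 folds.
#'
#' @param cohort An `sh_cohort` or a character vector of mouse ids.
#' @return Tibble with columns `fold`, `test_mouse` and the list-column
#'   `train_mice`.
#' @export
lomo_folds <- function(cohort) {
  ids <- if (inherits(cohort, "sh_cohort"))
    vapply(cohort$mice, `[[`, "", "mouse_id") else as.character(cohort)
  if (anyDuplicated(ids)) abort("duplicate mouse_id in cohort")
  if (length(ids) < 2) abort("need at least 2 mice for cross-validation")
  tibble::tibble(
    fold = seq_along(ids),
    test_mouse = ids,
    train_mice = lapply(seq_along(ids), function(i) ids[-i])
  )
}

#' Pixel-level confusion matrix
#'
#' Counts are tabulated over the supplied (already edge-excluded) pixels,
#' rows = truth, columns = predicted, over a fixed class list so absent
#' classes keep their row.
#'
#' @param truth,predicted Equal-length label vectors (class names).
#' @param classes Ordered class list; defaults to the classes present.
#' @return An object of class `sh_confusion` with elements `classes`,
#'   `counts`, `rates` (row-normalized), `accuracy`, `tpr`.
#' @export
pixel_confusion <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    abort("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    abort(sprintf("label(s) outside the class set: %s", paste(bad, collapse = ", ")))
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs == 0, 1, rs)
  acc <- if (sum(counts) == 0) NA_real_ else sum(diag(counts)) / sum(counts)
  tpr <- ifelse(rs == 0, NA_real_, diag(counts) / rs)
  names(tpr) <- classes
  structure(list(classes = classes, counts = counts, rates = rates,
                 accuracy = acc, tpr = tpr),
            class = "sh_confusion")
}

#' @export
print.sh_confusion <- function(x, ...) {
  cat(sprintf("<sh_confusion> %d classes, accuracy %.3f\n",
              length(x$classes), x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Majority-filter a label mask
#'
#' Each tissue pixel is replaced by the modal label of its `window x window`
#' neighbourhood; background (0) never votes and is never overwritten, and
#' ties keep the center pixel's label.
#'
#' @param mask Integer label matrix.
#' @param window Odd window size (default 5).
#' @return Filtered integer matrix.
#' @export
majority_filter <- function(mask, window = 5) {
  if (window < 1 || window %% 2 == 0) abort("window must be odd and >= 1")
  storage.mode(mask) <- "integer"
  .majority_filter_cpp(mask, as.integer(window))
}

#' Tissue-level ROC from pathology pixel counts
#'
#' Each mouse is reduced to its count of pathology-class pixels (after
#' majority filtering); a mouse is called pathological iff its count exceeds
#' a threshold, and the threshold is swept over all distinct counts (plus
#' both ends) to trace the ROC. The area under the curve is the trapezoidal
#' integral over the (FPR, TPR) path, which equals the Mann-Whitney
#' statistic U / (n1 * n2) with ties counted 1/2. The operating threshold is
#' chosen from the healthy (control) group: the maximum healthy count.
#'
#' @param counts Tibble/data frame with columns `mouse_id`, `count`,
#'   `truth` (`healthy` / `pathological`).
#' @return An object of class `sh_roc` with the threshold sweep, `auc`,
#'   Hanley-McNeil `se` and `chosen_threshold`.
#' @export
tissue_roc <- function(counts) {
  stopifnot(all(c("mouse_id", "count", "truth") %in% names(counts)))
  truth <- counts$truth
  if (!all(truth %in% c("healthy", "pathological")))
    abort("truth must be 'healthy' or 'pathological'")
  n_h <- sum(truth == "healthy"); n_p <- sum(truth == "pathological")
  if (n_h == 0 || n_p == 0)
    abort("need at least one healthy and one pathological mouse")
  x <- counts$count
  thr <- c(-Inf, sort(unique(x)))
  tpr <- vapply(thr, function(t) sum(x > t & truth == "pathological") / n_p,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(x > t & truth == "healthy") / n_h,
                numeric(1))
  # thresholds ascend, so (fpr, tpr) descends from (1,1) to (0,0); reverse
  # to integrate the path from the origin
  fpr <- rev(fpr); tpr <- rev(tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(per_mouse = tibble::as_tibble(counts),
         thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
         se = auc_se(auc, n_h, n_p),
         chosen_threshold = max(x[truth == "healthy"])),
    class = "sh_roc"
  )
}

#' @export
print.sh_roc <- function(x, ...) {
  cat(sprintf("<sh_roc> AUC %.3f (SE %.3f), threshold > %g pathology pixels\n",
              x$auc, x$se, x$chosen_threshold))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `se = sqrt((A(1-A) + (n_p - 1)(Q1 - A^2) + (n_h - 1)(Q2 - A^2)) /
#' (n_h * n_p))` with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc Area under the curve in [0, 1].
#' @param n_healthy,n_pathological Group sizes (>= 1).
#' @return Standard error (>= 0).
#' @export
auc_se <- function(auc, n_healthy, n_pathological) {
  if (auc < 0 || auc > 1) abort("auc must lie in [0, 1]")
  if (n_healthy < 1 || n_pathological < 1) abort("group sizes must be >= 1")
  A <- auc
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_pathological - 1) * (q1 - A^2) +
          (n_healthy - 1) * (q2 - A^2)) / (n_healthy * n_pathological)
  sqrt(max(v, 0))
}

#' Run the full leave-one-mouse-out evaluation of a cohort
#'
#' The end-to-end pipeline: each cube is MNF-denoised and featurized once;
#' then, per leave-one-mouse-out fold, the detailed (7-class) and rapid
#' (3-class) models are trained on the other mice and scored on the held-out
#' mouse's interior (edge-excluded) labeled pixels; the rapid model also
#' predicts the full image, which is majority-filtered and reduced to the
#' pathology pixel count feeding the tissue-level ROC.
#'
#' @param cohort An `sh_cohort` ([make_cohort()]).
#' @param detailed_spec,rapid_spec Model specs; defaults 50 / 25 trees.
#' @param k MNF components retained (default 20).
#' @param region_table Region table (default 42-region surrogate).
#' @param window Majority-filter window (default 5).
#' @param denoise Apply MNF denoising before featurization (default TRUE).
#' @param keep_features Also return the per-mouse feature tables and
#'   edge-interior flags (default FALSE), for downstream reuse such as the
#'   metric-count sweep.
#' @return An object of class `sh_eval`: pooled `confusion_detailed` (7x7)
#'   and `confusion_rapid` (3x3), per-fold matrices, `roc` (an `sh_roc`),
#'   `per_mouse` counts and configuration.
#' @export
run_full_evaluation <- function(cohort,
                                detailed_spec = model_spec("detailed"),
                                rapid_spec = model_spec("rapid"),
                                k = 20,
                                region_table = default_region_table(),
                                window = 5,
                                denoise = TRUE,
                                keep_features = FALSE) {
  stopifnot(inherits(cohort, "sh_cohort"))
  ids <- vapply(cohort$mice, `[[`, "", "mouse_id")

  # stage 1: denoise + featurize each mouse once
  feats <- vector("list", length(ids))
  interior <- vector("list", length(ids))
  for (i in seq_along(cohort$mice)) {
    m <- cohort$mice[[i]]
    cube <- if (denoise) mnf_denoise(m$cube, k = k) else m$cube
    feats[[i]] <- build_feature_table(cube, m$labels, region_table)
    keepm <- exclude_edge_pixels(m$labels, m$cube$tissue_mask)
    interior[[i]] <- keepm[cbind(feats[[i]]$row, feats[[i]]$col)]
    cohort$mice[[i]]$denoised <- cube
  }
  names(feats) <- ids

  folds <- lomo_folds(cohort)
  det_truth <- det_pred <- rap_truth <- rap_pred <- character(0)
  fold_confusions <- vector("list", nrow(folds))
  per_mouse <- tibble::tibble(mouse_id = ids, count = NA_real_,
                              truth = unname(cohort$tissue_truth[ids]))

  for (f in seq_len(nrow(folds))) {
    te <- folds$test_mouse[f]
    tr_tb <- dplyr::bind_rows(lapply(which(ids != te), function(i)
      feats[[i]][interior[[i]], , drop = FALSE]))
    i_te <- which(ids == te)
    te_tb <- feats[[i_te]][interior[[i_te]], , drop = FALSE]

    det_fit <- train_model(tr_tb, detailed_spec)
    p_det <- as.character(predict_features(det_fit, te_tb))
    det_truth <- c(det_truth, te_tb$label)
    det_pred <- c(det_pred, p_det)

    rap_fit <- train_model(tr_tb, rapid_spec)
    y_rap <- map_labels(te_tb$label, rapid_spec)
    sel <- !is.na(y_rap)
    p_rap <- as.character(predict_features(rap_fit, te_tb[sel, , drop = FALSE]))
    rap_truth <- c(rap_truth, y_rap[sel])
    rap_pred <- c(rap_pred, p_rap)

    fold_confusions[[f]] <- pixel_confusion(
      te_tb$label, p_det, classes = names(SH_CLASSES)[-1])

    # whole-image rapid prediction -> majority filter -> pathology count
    pim <- predict_image(rap_fit, cohort$mice[[i_te]]$denoised,
                         region_table, features = feats[[i_te]])
    filtered <- majority_filter(pim$mask, window)
    per_mouse$count[per_mouse$mouse_id == te] <-
      sum(filtered == SH_RAPID_CLASSES["pathology"])
  }

  structure(
    list(
      features = if (keep_features) feats,
      interior = if (keep_features) interior,
      confusion_detailed = pixel_confusion(det_truth, det_pred,
                                           classes = names(SH_CLASSES)[-1]),
      confusion_rapid = pixel_confusion(rap_truth, rap_pred,
                                        classes = names(SH_RAPID_CLASSES)),
      fold_confusions = fold_confusions,
      roc = tissue_roc(per_mouse),
      per_mouse = per_mouse,
      config = list(k = k, window = window,
                    detailed_spec = detailed_spec, rapid_spec = rapid_spec,
                    n_regions = nrow(region_table), denoise = denoise)
    ),
    class = "sh_eval"
  )
}

#' @export
print.sh_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "<sh_eval> %d mice\n  detailed (7-class) pixel accuracy: %.3f\n",
    "  rapid (3-class) pixel accuracy:    %.3f\n",
    "  tissue-level AUC: %.3f (SE %.3f)\n"),
    nrow(x$per_mouse), x$confusion_detailed$accuracy,
    x$confusion_rapid$accuracy, x$roc$auc, x$roc$se))
  invisible(x)
}
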