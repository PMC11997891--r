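#' Random-forest model specification
#'
#' Two operating modes mirror the published pipeline: a `detailed`
#' seven-class model (50 trees) for PanIN-level classification and a `rapid`
#' three-class screening model (25 trees) distinguishing pathology
#' (cancer + PanIN), fiber and benign tissue. A third `importance` mode
#' (100 trees) is used only to rank metrics for the rapid model. Training
#' pixels are balanced by per-class downsampling to the smallest class,
#' capped at `max_per_class`.
#'
#' @param mode `"detailed"`, `"rapid"` or `"importance"`.
#' @param n_trees Tree count; defaults 50 / 25 / 100 by mode.
#' @param class_map Named mapping from the seven tissue classes to rapid
#'   classes (`NA` = excluded from rapid training). Only used by the rapid
#'   and importance modes.
#' @param feature_subset Optional character vector of metric names to train
#'   on (e.g. the top-k from [rank_metrics()]).
#' @param max_per_class Cap on balanced per-class training pixels.
#' @param seed Integer seed making training deterministic.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(mode = c("detailed", "rapid", "importance"),
                       n_trees = NULL,
                       class_map = default_rapid_map(),
                       feature_subset = NULL,
                       max_per_class = 300L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_trees))
    n_trees <- switch(mode, detailed = 50L, rapid = 25L, importance = 100L)
  if (n_trees < 1) abort("n_trees must be >= 1")
  structure(
    list(mode = mode, n_trees = as.integer(n_trees), class_map = class_map,
         feature_subset = feature_subset,
         max_per_class = as.integer(max_per_class), seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @rdname model_spec
#' @export
default_rapid_map <- function() {
  c(benign = "benign", fiber = "fiber", cancer = "pathology",
    PanIN = "pathology", blood = NA, inflammation = NA, necrosis = NA)
}

feature_columns <- function(table) {
  setdiff(names(table), c("mouse_id", "row", "col", "label"))
}

# map labels for the spec's mode; rows excluded by the map get NA
map_labels <- function(label, spec) {
  if (spec$mode == "detailed") return(label)
  unname(spec$class_map[label])
}

#' Train a random-forest pixel classifier
#'
#' @param table Feature table ([build_feature_table()] output, labeled).
#' @param spec A [model_spec()].
#' @return An object of class `sh_model`: the fitted ensemble plus the
#'   class list and normalized feature importances.
#' @export
train_model <- function(table, spec = model_spec("detailed")) {
  stopifnot(inherits(spec, "model_spec"))
  feats <- feature_columns(table)
  if (!is.null(spec$feature_subset)) {
    missing <- setdiff(spec$feature_subset, feats)
    if (length(missing))
      abort(sprintf("unknown feature(s) in feature_subset: %s",
                    paste(head(missing, 3), collapse = ", ")))
    feats <- spec$feature_subset
  }
  y <- map_labels(table$label, spec)
  keep <- !is.na(y)
  n_excluded <- sum(!keep)
  tb <- table[keep, , drop = FALSE]
  y <- y[keep]
  X <- as.matrix(tb[, feats, drop = FALSE])
  if (anyNA(X)) abort("feature table contains NA values")
  classes <- sort(unique(y))
  if (length(classes) < 2)
    abort("fewer than 2 classes present after class mapping")

  fit <- with_seed(spec$seed, {
    # balanced downsampling to the smallest class (capped)
    n_min <- min(table(y))
    n_take <- min(n_min, spec$max_per_class)
    sel <- unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      if (length(i) > n_take) sample(i, n_take) else i
    }), use.names = FALSE)
    randomForest::randomForest(
      x = X[sel, , drop = FALSE], y = factor(y[sel], levels = classes),
      ntree = spec$n_trees, importance = FALSE
    )
  })
  imp <- fit$importance[, "MeanDecreaseGini"]
  s <- sum(imp)
  importances <- if (s > 0) imp / s else rep(1 / length(imp), length(imp))
  names(importances) <- feats
  structure(
    list(spec = spec, fit = fit, classes = classes, features = feats,
         importances = importances, n_train = length(fit$y),
         n_excluded = n_excluded),
    class = "sh_model"
  )
}

#' @export
print.sh_model <- function(x, ...) {
  cat(sprintf("<sh_model> %s: %d trees, %d features, classes: %s (n_train %d)\n",
              x$spec$mode, x$spec$n_trees, length(x$features),
              paste(x$classes, collapse = "/"), x$n_train))
  invisible(x)
}

predict_features <- function(model, table, type = "response") {
  feats <- model$features
  missing <- setdiff(feats, names(table))
  if (length(missing))
    abort(sprintf("feature table lacks %d column(s) the model was trained on",
                  length(missing)))
  X <- as.matrix(table[, feats, drop = FALSE])
  predict(model$fit, X, type = type)
}

#' Predict a class-label image from a cube
#'
#' Computes the feature table of every tissue pixel of the cube and runs the
#' classifier, returning a label mask in the model's code space (the fixed
#' seven-class codes for detailed models; benign = 1, pathology = 2,
#' fiber = 3 for rapid models) plus per-pixel class probabilities.
#' Background stays 0.
#'
#' @param model An [train_model()] result.
#' @param cube A [hyper_cube()].
#' @param region_table Region table used at training time.
#' @param features Optional precomputed feature table for the cube
#'   (all tissue pixels), to avoid recomputation.
#' @return List with `mask` (integer matrix), `prob` (pixels x classes
#'   matrix with `row`/`col` attributes), `classes`, `codes`.
#' @export
predict_image <- function(model, cube, region_table = default_region_table(),
                          features = NULL) {
  d <- dim(cube$data)
  mask <- matrix(0L, d[1], d[2])
  if (is.null(features))
    features <- if (sum(cube$tissue_mask) == 0) NULL
      else build_feature_table(cube, labels = NULL, region_table = region_table)
  if (is.null(features) || nrow(features) == 0) {
    return(list(mask = mask, prob = NULL, classes = model$classes,
                codes = model_codes(model)))
  }
  prob <- predict_features(model, features, type = "prob")
  cls <- model$classes[max.col(prob, ties.method = "first")]
  codes <- model_codes(model)
  mask[cbind(features$row, features$col)] <- codes[cls]
  list(mask = mask, prob = prob, classes = model$classes, codes = codes,
       row = features$row, col = features$col)
}

model_codes <- function(model) {
  if (model$spec$mode == "detailed") SH_CLASSES[model$classes]
  else SH_RAPID_CLASSES[model$classes]
}

#' Rank metrics by random-forest importance
#'
#' Trains the 100-tree importance model on all metrics and returns them
#' sorted by decreasing (normalized Gini) importance, ties broken by
#' feature-column order.
#'
#' @param table Labeled feature table.
#' @param spec A [model_spec()] with `mode = "importance"`.
#' @return Character vector of metric names, most important first, with the
#'   normalized importances as the `importance` attribute.
#' @export
rank_metrics <- function(table, spec = model_spec("importance")) {
  if (spec$mode != "importance")
    abort("rank_metrics expects a spec with mode = 'importance'")
  model <- train_model(table, spec)
  imp <- model$importances
  ord <- order(-imp, seq_along(imp))
  out <- names(imp)[ord]
  attr(out, "importance") <- imp[ord]
  out
}

#' Accuracy versus number of top-ranked metrics
#'
#' For each metric count `k`, trains the rapid model on the top-`k` ranked
#' metrics and records its leave-one-mouse-out pixel accuracy. The chosen
#' count is the smallest `k` whose accuracy is within 0.5 accuracy points
#' (0.005) of the curve's maximum — the smallest feature set that keeps
#' performance essentially at its best.
#'
#' @param table Labeled multi-mouse feature table (with `mouse_id`).
#' @param ranked_metrics Output of [rank_metrics()].
#' @param counts Integer vector of metric counts to evaluate.
#' @param spec Rapid [model_spec()].
#' @param edge_keep Optional logical vector marking rows retained after edge
#'   exclusion.
#' @return A tibble of class `sh_sweep` with columns `k`, `accuracy`;
#'   attributes `chosen_k` and `chosen_metrics`.
#' @export
metric_count_sweep <- function(table, ranked_metrics, counts = c(1:8, 10, 12),
                               spec = model_spec("rapid"), edge_keep = NULL) {
  counts <- sort(unique(as.integer(counts)))
  if (length(counts) == 0) abort("counts is empty")
  if (any(counts < 1) || any(counts > length(ranked_metrics)))
    abort("counts must lie within [1, number of metrics]")
  if (!is.null(edge_keep)) table <- table[edge_keep, , drop = FALSE]
  acc <- vapply(counts, function(k) {
    s <- spec
    s$feature_subset <- ranked_metrics[seq_len(k)]
    lomo_accuracy(table, s)
  }, numeric(1))
  out <- tibble::tibble(k = counts, accuracy = acc)
  best <- max(acc)
  chosen <- counts[which(acc >= best - 0.005)[1]]
  attr(out, "chosen_k") <- chosen
  attr(out, "chosen_metrics") <- ranked_metrics[seq_len(chosen)]
  class(out) <- c("sh_sweep", class(out))
  out
}

# pooled leave-one-mouse-out pixel accuracy of a spec on a feature table
lomo_accuracy <- function(table, spec) {
  y <- map_labels(table$label, spec)
  keep <- !is.na(y)
  tb <- table[keep, , drop = FALSE]
  y <- y[keep]
  mice <- unique(tb$mouse_id)
  correct <- 0L; total <- 0L
  for (m in mice) {
    te <- tb$mouse_id == m
    if (!any(te) || all(te)) next
    if (length(unique(y[!te])) < 2) next
    fit <- train_model(tb[!te, , drop = FALSE], spec)
    pred <- as.character(predict_features(fit, tb[te, , drop = FALSE]))
    correct <- correct + sum(pred == y[te])
    total <- total + sum(te)
  }
  if (total == 0) abort("no test pixels in any fold")
  correct / total
}
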