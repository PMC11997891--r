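#' Tidy a confusion matrix into long form
#'
#' @param x An `sh_confusion`.
#' @param ... Unused.
#' @return Tibble with `truth`, `predicted`, `n`, `rate`.
#' @export
tidy.sh_confusion <- function(x, ...) {
  tb <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(tb) <- c("truth", "predicted", "n")
  tb$rate <- as.vector(x$rates)
  tibble::as_tibble(tb)
}

#' @rdname tidy.sh_confusion
#' @export
glance.sh_confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$counts),
                 n_classes = length(x$classes))
}

#' Tidy the threshold sweep of a tissue-level ROC
#'
#' @param x An `sh_roc`.
#' @param ... Unused.
#' @return Tibble with `fpr`, `tpr` along the sweep.
#' @export
tidy.sh_roc <- function(x, ...) {
  tibble::tibble(fpr = x$fpr, tpr = x$tpr)
}

#' @rdname tidy.sh_roc
#' @export
glance.sh_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se,
                 chosen_threshold = x$chosen_threshold,
                 n_healthy = sum(x$per_mouse$truth == "healthy"),
                 n_pathological = sum(x$per_mouse$truth == "pathological"))
}

#' Tidy a trained model's feature importances
#'
#' @param x An `sh_model`.
#' @param ... Unused.
#' @return Tibble with `metric`, `importance`, sorted descending.
#' @export
tidy.sh_model <- function(x, ...) {
  tibble::tibble(metric = names(x$importances),
                 importance = unname(x$importances)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.sh_model
#' @export
glance.sh_model <- function(x, ...) {
  tibble::tibble(mode = x$spec$mode, n_trees = x$spec$n_trees,
                 n_features = length(x$features),
                 n_classes = length(x$classes), n_train = x$n_train)
}

#' Summarize a full cohort evaluation
#'
#' @param x An `sh_eval`.
#' @param ... Unused.
#' @return One-row tibble with the headline numbers of the evaluation.
#' @export
glance.sh_eval <- function(x, ...) {
  tibble::tibble(
    detailed_accuracy = x$confusion_detailed$accuracy,
    rapid_accuracy = x$confusion_rapid$accuracy,
    tissue_auc = x$roc$auc,
    tissue_auc_se = x$roc$se,
    chosen_threshold = x$roc$chosen_threshold,
    n_mice = nrow(x$per_mouse)
  )
}

#' @rdname glance.sh_eval
#' @export
tidy.sh_eval <- function(x, ...) x$per_mouse
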