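# Evaluation metrics: accuracy, recall, precision, F1 (macro-averaged for
# three classes), AUC (one-vs-rest, via pROC) and AUPR (average
# precision, computed in-package by the standard step sum).

average_precision <- function(truth01, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- truth01[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1L]) / sum(y)
}

safe_auc <- function(truth01, scores) {
  if (length(unique(truth01)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth01, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Classification metrics
#'
#' Computes accuracy, recall, precision and F1 from the confusion counts
#' (positive class = 1 for binary labels; macro averages over classes
#' otherwise), plus balanced accuracy, and AUC / AUPR from `scores` when
#' supplied (one-vs-rest for more than two classes). With a single-class
#' truth the ranking metrics are omitted with a warning.
#'
#' @param truth Integer true labels.
#' @param estimate Integer predicted labels.
#' @param scores Optional: a numeric vector of positive-class scores
#'   (binary) or an `n x K` probability matrix.
#' @return A one-row tibble with `acc`, `rec`, `pre`, `f1`,
#'   `balanced_acc`, `auc`, `aupr`, `n`; the confusion matrix is attached
#'   as attribute `confusion`.
#' @export
compute_metrics <- function(truth, estimate, scores = NULL) {
  abort_if(length(truth) != length(estimate),
           "`truth` and `estimate` must have equal length")
  classes <- sort(unique(c(truth, estimate)))
  k <- length(classes)
  conf <- table(factor(truth, levels = classes),
                factor(estimate, levels = classes))
  acc <- sum(diag(conf)) / sum(conf)

  per_class <- function(cls) {
    tp <- conf[as.character(cls), as.character(cls)]
    fn <- sum(conf[as.character(cls), ]) - tp
    fp <- sum(conf[, as.character(cls)]) - tp
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (!is.na(rec) && pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    c(rec = rec, pre = pre, f1 = f1)
  }

  if (k <= 2L && all(classes %in% 0:1)) {
    m <- per_class(1L)
    balanced <- mean(vapply(classes, function(cl) per_class(cl)["rec"],
                            numeric(1)), na.rm = TRUE)
  } else {
    ms <- vapply(classes, per_class, numeric(3))
    m <- rowMeans(ms, na.rm = TRUE)
    balanced <- mean(ms["rec", ], na.rm = TRUE)
  }

  auc <- aupr <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2L) {
      rlang::warn("single-class truth: AUC/AUPR omitted")
    } else if (is.matrix(scores)) {
      present <- sort(unique(truth))
      aucs <- vapply(present, function(cl) {
        safe_auc(as.integer(truth == cl), scores[, cl + 1L])
      }, numeric(1))
      auprs <- vapply(present, function(cl) {
        average_precision(as.integer(truth == cl), scores[, cl + 1L])
      }, numeric(1))
      auc <- mean(aucs, na.rm = TRUE)
      aupr <- mean(auprs, na.rm = TRUE)
    } else {
      auc <- safe_auc(as.integer(truth == 1L), scores)
      aupr <- average_precision(as.integer(truth == 1L), scores)
    }
  }

  out <- tibble::tibble(acc = acc, rec = unname(m["rec"]),
                        pre = unname(m["pre"]), f1 = unname(m["f1"]),
                        balanced_acc = balanced, auc = auc, aupr = aupr,
                        n = length(truth))
  attr(out, "confusion") <- conf
  out
}
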