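#' Confusion matrix over a fixed class set
#'
#' Rows are true classes, columns predicted classes, both over the full
#' class set (so absent classes keep zero rows/columns).
#'
#' @param truth,pred factors or character vectors
#' @param classes class levels (default: levels of `truth`)
#' @return square integer matrix
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  classes <- classes %||% levels(as.factor(truth))
  tab <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(truth = classes, pred = classes))
  m
}

#' Classification accuracy from a confusion matrix
#' @param cm square confusion matrix (rows truth, columns predictions)
#' @return trace / total
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) return(NA_real_)
  sum(diag(cm)) / sum(cm)
}

#' Weighted F1 score from a confusion matrix
#'
#' Per-class F1 (harmonic mean of precision and recall) averaged with
#' weights proportional to the number of true instances of each class.
#' Classes with zero precision + recall contribute an F1 of 0; classes
#' with zero support contribute nothing.
#'
#' @param cm square non-negative confusion matrix (rows truth, columns
#'   predictions)
#' @return scalar in [0, 1]
#' @export
weighted_f1 <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) == 0 || nrow(cm) != ncol(cm)) {
    stop_emofuse("metrics", "confusion matrix must be a non-empty square matrix")
  }
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (sum(support) == 0) return(NA_real_)
  sum(support / sum(support) * f1)
}
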