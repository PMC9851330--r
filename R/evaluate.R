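# Evaluation metrics with temperate as the positive class: confusion counts,
# sensitivity/specificity/accuracy, and the ROC curve with trapezoidal AUC.

#' Confusion counts (temperate = positive class)
#'
#' TP counts temperate records called temperate, TN virulent records called
#' virulent. Records called "unclassified" are excluded from the counts and
#' reported separately.
#'
#' @param labels Character vector in {temperate, virulent}.
#' @param calls Character vector in {temperate, virulent, unclassified}.
#' @return List: TP, FN, TN, FP, unclassified.
#' @export
confusion_counts <- function(labels, calls) {
  stopifnot(length(labels) == length(calls))
  bad <- setdiff(unique(labels), c("temperate", "virulent"))
  if (length(bad))
    stop("label(s) outside {temperate, virulent}: ", paste(bad, collapse = ", "))
  uncl <- calls == "unclassified"
  l <- labels[!uncl]; c2 <- calls[!uncl]
  list(TP = sum(l == "temperate" & c2 == "temperate"),
       FN = sum(l == "temperate" & c2 == "virulent"),
       TN = sum(l == "virulent" & c2 == "virulent"),
       FP = sum(l == "virulent" & c2 == "temperate"),
       unclassified = sum(uncl))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+FN+TN+FP). An empty denominator gives NaN.
#'
#' @param counts As returned by [confusion_counts()].
#' @return Named numeric vector: sensitivity, specificity, accuracy.
#' @export
classification_metrics <- function(counts) {
  with(counts, c(
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NaN,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NaN,
    accuracy = if (TP + FN + TN + FP > 0)
      (TP + TN) / (TP + FN + TN + FP) else NaN))
}

#' ROC curve and AUCROC
#'
#' Thresholds the temperate-probability scores at every unique value (equal
#' scores grouped), accumulating true/false positive rates, and integrates by
#' the trapezoidal rule — which makes the AUC equal to the Mann-Whitney
#' U statistic divided by n+ * n- (with the usual 1/2 credit for ties).
#'
#' @param scores Finite numeric scores (higher = more temperate-like).
#' @param labels Character vector in {temperate, virulent}; both classes must
#'   be present.
#' @return List: `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == "temperate"
  neg <- labels == "virulent"
  if (!any(pos) || !any(neg))
    stop("both classes must be present to compute a ROC curve")
  if (!all(pos | neg))
    stop("label(s) outside {temperate, virulent}")
  np <- sum(pos); nn <- sum(neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp_end <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each tie group
  thr <- s[grp_end]
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / nn),
                      tpr = c(0, tp / np))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1L) +
                                  utils::tail(curve$tpr, -1L)) / 2)
  list(curve = curve, auc = auc)
}

#' Write evaluation outputs
#'
#' @param predictions Data.frame from [predict_lifestyle()] plus a matching
#'   `label` column, or separate `labels`.
#' @param labels Character labels aligned with `predictions` rows.
#' @param out_json Path for the metrics JSON (counts + metrics + AUC).
#' @param roc_csv Optional path for the ROC curve points CSV.
#' @return The metrics list, invisibly.
#' @export
evaluate_predictions <- function(predictions, labels, out_json = NULL,
                                 roc_csv = NULL) {
  cc <- confusion_counts(labels, predictions$call)
  met <- classification_metrics(cc)
  classified <- predictions$call != "unclassified"
  roc <- if (length(unique(labels[classified])) == 2L)
    roc_auc(predictions$p_temperate[classified], labels[classified])
  else NULL
  res <- list(counts = cc, metrics = as.list(met),
              auc = if (is.null(roc)) NA_real_ else roc$auc)
  if (!is.null(out_json))
    jsonlite::write_json(res, out_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_csv) && !is.null(roc))
    utils::write.csv(roc$curve, roc_csv, row.names = FALSE)
  invisible(res)
}
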