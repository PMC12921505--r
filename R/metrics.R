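# Binary-classification metrics with pathogenic as the positive class:
# confusion counts, MCC, F1, score-driven ROC/AUC, and the Youden-optimal
# threshold (max TPR - FPR) used to fix operating points.

as_binary <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- !x %in% c("benign", "pathogenic")
    if (any(bad)) stop("NonBinary: ", what, " must be benign/pathogenic or 0/1",
                       call. = FALSE)
    return(as.integer(x == "pathogenic"))
  }
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("NonBinary: ", what, " must be 0/1",
                                   call. = FALSE)
  x
}

#' Confusion counts (pathogenic = positive)
#'
#' @param labels true labels: 0/1 or `"benign"`/`"pathogenic"`.
#' @param calls predicted labels, same coding.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, calls) {
  y <- as_binary(labels, "labels"); p <- as_binary(calls, "calls")
  if (length(y) != length(p))
    stop("LengthMismatch: labels and calls differ in length", call. = FALSE)
  structure(list(TP = sum(y == 1L & p == 1L), FP = sum(y == 0L & p == 1L),
                 TN = sum(y == 0L & p == 0L), FN = sum(y == 1L & p == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Row-normalized confusion matrix (percent within each true class)
#'
#' @param c a `confusion_counts`.
#' @return 2x2 matrix of percentages, rows = true class, columns = call.
#' @export
confusion_percent <- function(c) {
  m <- matrix(c(c$TN, c$FP, c$FN, c$TP), nrow = 2, byrow = TRUE,
              dimnames = list(true = c("benign", "pathogenic"),
                              call = c("benign", "pathogenic")))
  sweep(m, 1L, pmax(rowSums(m), 1L), `/`) * 100
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' conventional value 0 when any marginal factor is zero.
#'
#' @param c a `confusion_counts`.
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(c) {
  den <- as.numeric(c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (den == 0) return(0)
  ((as.numeric(c$TP) * c$TN) - (as.numeric(c$FP) * c$FN)) / sqrt(den)
}

#' F1 score
#'
#' `2 TP / (2 TP + FP + FN)`; 0 when the denominator is 0.
#'
#' @param c a `confusion_counts`.
#' @return A number in `[0, 1]`.
#' @export
f1 <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(0)
  2 * c$TP / den
}

# Orient scores so that larger means more pathogenic.
pathogenicity_direction <- function(scores, orientation) {
  orientation <- match.arg(orientation,
                           c("lower_is_pathogenic", "higher_is_pathogenic"))
  if (orientation == "lower_is_pathogenic") -scores else scores
}

#' ROC curve and AUC
#'
#' Thresholds are swept over the distinct observed score values (ties flip
#' together); the curve includes the (0,0) and (1,1) endpoints and the AUC is
#' the trapezoid area, which equals the pairwise concordance probability with
#' half credit for ties.
#'
#' @param scores numeric scores.
#' @param labels true labels (0/1 or benign/pathogenic).
#' @param orientation `"lower_is_pathogenic"` or `"higher_is_pathogenic"`.
#' @return A list of class `roc_curve`: `points` (data.frame `fpr`, `tpr`,
#'   `threshold` on the original score scale, `NA` at the endpoints), `auc`,
#'   and `orientation`.
#' @export
roc_and_auc <- function(scores, labels, orientation = "higher_is_pathogenic") {
  y <- as_binary(labels, "labels")
  if (length(unique(y)) < 2L)
    stop("SingleClass: both classes must be present", call. = FALSE)
  if (length(scores) != length(y))
    stop("LengthMismatch", call. = FALSE)
  s <- pathogenicity_direction(scores, orientation)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  # sweep in decreasing oriented score; each distinct value moves its whole
  # tie group from "benign" to "pathogenic"
  o <- order(s, decreasing = TRUE)
  s_ord <- s[o]; y_ord <- y[o]
  grp <- cumsum(!duplicated(s_ord))
  tp <- cumsum(y_ord)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - y_ord)[!duplicated(grp, fromLast = TRUE)]
  thr_oriented <- s_ord[!duplicated(grp)]
  pts <- data.frame(fpr = c(0, fp / nn, 1), tpr = c(0, tp / np, 1),
                    threshold = c(NA,
                                  if (orientation == "lower_is_pathogenic")
                                    -thr_oriented else thr_oriented,
                                  NA))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, orientation = orientation),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f (%s)\n",
              nrow(x$points), x$auc, x$orientation))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Returns the observed score value maximizing `TPR - FPR` when used as the
#' decision threshold under the package's classification rule
#' (strict inequality, tie called benign; see [classify()]). Ties in the
#' maximum are broken toward lower FPR, then toward the more conservative
#' threshold (fewer pathogenic calls).
#'
#' @inheritParams roc_and_auc
#' @return The optimal threshold (a single score value).
#' @export
optimal_threshold <- function(scores, labels, orientation = "higher_is_pathogenic") {
  y <- as_binary(labels, "labels")
  if (length(unique(y)) < 2L)
    stop("SingleClass: both classes must be present", call. = FALSE)
  orientation <- match.arg(orientation,
                           c("lower_is_pathogenic", "higher_is_pathogenic"))
  np <- sum(y == 1L); nn <- sum(y == 0L)
  cand <- sort(unique(scores))
  stats_at <- vapply(cand, function(t) {
    call <- classify(scores, threshold = t, orientation = orientation)
    p <- call == "pathogenic"
    c(j = sum(p & y == 1L) / np - sum(p & y == 0L) / nn,
      fpr = sum(p & y == 0L) / nn, ncalls = sum(p))
  }, numeric(3))
  best <- which(stats_at["j", ] == max(stats_at["j", ]))
  best <- best[stats_at["fpr", best] == min(stats_at["fpr", best])]
  best <- best[which.min(stats_at["ncalls", best])]
  cand[best]
}

#' Full metrics report
#'
#' @param scores numeric scores.
#' @param labels true labels.
#' @param threshold decision threshold; if `NULL`, the Youden-optimal
#'   threshold is fit on these data.
#' @param orientation score orientation.
#' @return list with `confusion`, `mcc`, `f1`, `auc`, `threshold`,
#'   `confusion_percent`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL,
                            orientation = "higher_is_pathogenic") {
  if (is.null(threshold))
    threshold <- optimal_threshold(scores, labels, orientation)
  calls <- classify(scores, threshold = threshold, orientation = orientation)
  cc <- confusion(labels, calls)
  roc <- roc_and_auc(scores, labels, orientation)
  list(confusion = cc, mcc = mcc(cc), f1 = f1(cc), auc = roc$auc,
       threshold = threshold, confusion_percent = confusion_percent(cc),
       roc = roc)
}
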