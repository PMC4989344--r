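## Confusion-based performance measures, rank AUC and the Combined
## Performance Score.  Positive class = inside PPIR throughout.

#' Tally a confusion table
#'
#' @param labels,predictions Vectors over \{`inside`, `outside`\};
#'   positive class is `inside`.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("labels and predictions differ in length")
    labels <- as.character(labels)
    predictions <- as.character(predictions)
    bad <- setdiff(unique(c(labels, predictions)), c("inside", "outside"))
    if (length(bad))
        stop("labels must be 'inside'/'outside'; found: ",
             paste(bad, collapse = ", "))
    c(TP = sum(labels == "inside" & predictions == "inside"),
      FP = sum(labels == "outside" & predictions == "inside"),
      TN = sum(labels == "outside" & predictions == "outside"),
      FN = sum(labels == "inside" & predictions == "outside"))
}

#' Confusion-based performance measures
#'
#' Computes ACC, MCC, PPV (precision), F1, Sn (sensitivity/TPR),
#' Sp (specificity/TNR), FPR and FNR from the four counts:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}
#' \deqn{PPV = TP/(TP+FP), \quad F_1 = 2TP/(2TP+FP+FN)}
#' \deqn{S_n = TP/(TP+FN), \quad S_p = TN/(FP+TN)}
#' MCC returns 0 when any factor of its denominator is 0 (the standard
#' convention); PPV, F1, Sn and Sp return `NA` when their denominator
#' is 0.
#'
#' @param cc Named counts as returned by [confusionCounts()].
#' @return Named numeric vector `ACC`, `MCC`, `PPV`, `F1`, `Sn`, `Sp`,
#'   `FPR`, `FNR`.
#' @export
computeMetrics <- function(cc) {
    cc <- as.numeric(cc[c("TP", "FP", "TN", "FN")])
    if (anyNA(cc) || any(cc < 0)) stop("need non-negative TP/FP/TN/FN")
    TP <- cc[1L]; FP <- cc[2L]; TN <- cc[3L]; FN <- cc[4L]
    n <- TP + FP + TN + FN
    if (n == 0) stop("all counts are zero")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    mden <- (TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
    mcc <- if (mden == 0) 0 else (TP * TN - FP * FN) / sqrt(mden)
    sn <- ratio(TP, TP + FN)
    sp <- ratio(TN, FP + TN)
    c(ACC = (TP + TN) / n,
      MCC = mcc,
      PPV = ratio(TP, TP + FP),
      F1 = ratio(2 * TP, 2 * TP + FP + FN),
      Sn = sn, Sp = sp,
      FPR = 1 - sp, FNR = 1 - sn)
}

#' F-measure from precision and sensitivity
#'
#' Harmonic mean of PPV and Sn; algebraically equal to
#' `2TP/(2TP+FP+FN)`.
#'
#' @param ppv,sn Precision and sensitivity.
#' @return The F1 value.
#' @export
f1Score <- function(ppv, sn) 2 * ppv * sn / (ppv + sn)

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random positive
#' (`inside`) scores above a random negative, with ties contributing
#' one half; equals the trapezoidal area under the ROC curve.
#'
#' @param labels Vector over \{`inside`, `outside`\}; both classes
#'   must be present.
#' @param scores Real decision values, larger = more `inside`-like.
#' @return The AUC in \[0, 1\].
#' @export
aucScore <- function(labels, scores) {
    labels <- as.character(labels)
    if (length(labels) != length(scores))
        stop("labels and scores differ in length")
    pos <- labels == "inside"
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute AUC")
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Combined Performance Score
#'
#' `CPS = ACC + AUC + MCC`, the summation of three complementary
#' measures used to rank indices and feature prefixes; range
#' \[-1, 3\].
#'
#' @param report Named numeric vector (or 1-row data.frame) holding
#'   `ACC`, `AUC` and `MCC`.
#' @return The CPS value.
#' @export
cps <- function(report) {
    report <- unlist(report)
    need <- c("ACC", "AUC", "MCC")
    if (!all(need %in% names(report)) || anyNA(report[need]))
        stop("CPS needs ACC, AUC and MCC")
    unname(report[["ACC"]] + report[["AUC"]] + report[["MCC"]])
}
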