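#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    abort_input("confusion counts must be non-negative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Segmentation overlap metrics
#'
#' Dice coefficient `2 TP / (2 TP + FP + FN)`, Jaccard index
#' `TP / (TP + FP + FN)` and accuracy `(TP + TN) / (TP + TN + FP + FN)`.
#' Dice and Jaccard satisfy `DC = 2 JC / (1 + JC)`.
#'
#' @param c a [confusion_counts()].
#' @return Metric value in `[0, 1]`.
#' @export
dice <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) abort_input("Dice undefined: no positives in truth or prediction")
  2 * c$tp / den
}

#' @rdname dice
#' @export
jaccard <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) abort_input("Jaccard undefined: no positives in truth or prediction")
  c$tp / den
}

#' @rdname dice
#' @export
accuracy <- function(c) {
  den <- c$tp + c$tn + c$fp + c$fn
  if (den == 0) abort_input("accuracy undefined: empty confusion table")
  (c$tp + c$tn) / den
}

# Confusion counts of a predicted vs true binary mask / label vector.
confusion_of <- function(pred, truth) {
  confusion_counts(sum(pred & truth), sum(!pred & !truth),
                   sum(pred & !truth), sum(!pred & truth))
}

#' Per-class segmentation metrics for label masks
#'
#' Computes Dice/Jaccard/accuracy for the disc region (labels 1+2) and the
#' cup region (label 2), pooling pixels over all supplied mask pairs
#' (per-image averaging available via `per_image`).
#'
#' @param pred,truth a [label_mask()] or list of masks.
#' @param per_image average metrics over images instead of pooling pixels.
#' @return data.frame with columns `region`, `dice`, `jaccard`, `accuracy`.
#' @export
segmentation_metrics <- function(pred, truth, per_image = FALSE) {
  if (inherits(pred, "label_mask")) pred <- list(pred)
  if (inherits(truth, "label_mask")) truth <- list(truth)
  if (length(pred) != length(truth)) abort_input("mask lists differ in length")
  one <- function(p, t, region_fun) confusion_of(region_fun(p), region_fun(t))
  per_region <- function(region_fun) {
    cs <- Map(one, pred, truth, MoreArgs = list(region_fun = region_fun))
    if (per_image) {
      colMeans(do.call(rbind, lapply(cs, function(cc)
        c(dice = dice(cc), jaccard = jaccard(cc), accuracy = accuracy(cc)))))
    } else {
      tot <- confusion_counts(sum(vapply(cs, `[[`, 0, "tp")),
                              sum(vapply(cs, `[[`, 0, "tn")),
                              sum(vapply(cs, `[[`, 0, "fp")),
                              sum(vapply(cs, `[[`, 0, "fn")))
      c(dice = dice(tot), jaccard = jaccard(tot), accuracy = accuracy(tot))
    }
  }
  out <- rbind(disc = per_region(disc_region), cup = per_region(cup_region))
  data.frame(region = rownames(out), out, row.names = NULL)
}

check_binary_labels <- function(labels) {
  if (is.character(labels)) labels <- labels == "glaucoma"
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) abort_input("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation with midranks for ties,
#' which equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more glaucoma-like).
#' @param labels binary truth (logical, 0/1, or `"glaucoma"`/`"healthy"`).
#' @return AUROC in `[0, 1]`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort_input("length mismatch")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Candidate cut-points: midpoints between consecutive distinct scores,
# plus -Inf and +Inf.
roc_candidates <- function(scores) {
  s <- sort(unique(scores))
  c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
}

sens_spec_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(sens = sum(pred & labels == 1L) / sum(labels == 1L),
    spec = sum(!pred & labels == 0L) / sum(labels == 0L))
}

#' ROC-optimal threshold (closest point to the top-left corner)
#'
#' Among candidate cut-points (midpoints between consecutive distinct
#' scores plus infinities) selects the threshold minimizing the Euclidean
#' distance `sqrt((1 - sens)^2 + (1 - spec)^2)` of the ROC point to the
#' top-left corner; ties are resolved towards higher sensitivity.
#'
#' @inheritParams roc_auroc
#' @return The selected threshold.
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  cand <- roc_candidates(scores)
  ss <- t(vapply(cand, function(th) sens_spec_at(scores, labels, th), numeric(2)))
  dist <- sqrt((1 - ss[, "sens"])^2 + (1 - ss[, "spec"])^2)
  best <- which(dist <= min(dist) + 1e-12)
  best <- best[which.max(ss[best, "sens"])]
  cand[best]
}

#' Diagnostic summary at a threshold
#'
#' Sensitivity, specificity, PPV and NPV of the `score >= threshold` rule,
#' plus the AUROC of the scores.  An empty predicted class leaves the
#' corresponding predictive value `NA` rather than 0.
#'
#' @inheritParams roc_auroc
#' @param threshold decision threshold; defaults to [optimal_threshold()].
#' @return Object of class `diagnostic_summary`: a list with `auroc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `threshold`, `counts`.
#' @export
diagnostic_summary <- function(scores, labels, threshold = NULL) {
  labels <- check_binary_labels(labels)
  if (is.null(threshold)) threshold <- optimal_threshold(scores, labels)
  pred <- scores >= threshold
  cc <- confusion_of(pred, labels == 1L)
  structure(list(
    auroc = roc_auroc(scores, labels),
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp),
    ppv = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_,
    npv = if (cc$tn + cc$fn > 0) cc$tn / (cc$tn + cc$fn) else NA_real_,
    threshold = threshold, counts = cc), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f | sens %.3f spec %.3f PPV %s NPV %s @ threshold %.4g\n",
    x$auroc, x$sensitivity, x$specificity,
    ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
    ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv)), x$threshold))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, reports the
#' bias (mean of the differences `a - b`) and the 95% limits of agreement
#' `bias +/- 1.96 * SD` of the differences.
#'
#' @param values_a,values_b equal-length paired numeric vectors (n >= 2).
#' @return Object of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, `differences`, `means`.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) abort_input("paired vectors differ in length")
  if (length(values_a) < 2L) abort_input("need at least two pairs")
  d <- values_a - values_b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, differences = d,
                 means = (values_a + values_b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$differences)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, pch = 16,
                 col = grDevices::adjustcolor("black", 0.5),
                 xlab = "mean of methods", ylab = "difference (a - b)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "firebrick")
  invisible(x)
}
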