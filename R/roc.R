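#' ROC curve of a continuous marker against a binary outcome
#'
#' Builds the full ROC curve with thresholds placed at the midpoints
#' between consecutive distinct scores plus -Inf/+Inf sentinels. The
#' orientation is chosen automatically so that AUC >= 0.5: by default the
#' positive class (CR) is called when the marker is *above* the threshold;
#' if the marker is lower in the positive class the direction is flipped
#' and recorded.
#'
#' @param scores numeric marker values.
#' @param labels class labels (two classes must be present).
#' @param positive the positive class (default `"CR"` when present,
#'   otherwise the first factor level).
#' @return A `dwi_roc` data frame with columns `threshold`, `sensitivity`,
#'   `specificity`, `tpr`, `fpr` (curve ordered by increasing fpr), and
#'   attributes `auc`, `positive`, `higher_is_positive`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(.9, .8, .7, .75, .5, .4),
#'                c("CR", "CR", "CR", "non-CR", "non-CR", "non-CR"))
#' attr(r, "auc")
roc_curve <- function(scores, labels, positive = NULL) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- factor(labels[ok])
  if (nlevels(labels) != 2) {
    stop("ROC needs exactly two classes present in the labels", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if ("CR" %in% levels(labels)) "CR" else levels(labels)[1]
  }
  if (!positive %in% levels(labels)) {
    stop("positive class '", positive, "' not found in labels", call. = FALSE)
  }
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)

  # concordance (= AUC with ties counted 1/2) decides the orientation
  rk <- rank(scores)
  auc_raw <- (sum(rk[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  higher_is_positive <- auc_raw >= 0.5
  ws <- if (higher_is_positive) scores else -scores

  su <- sort(unique(ws))
  thr_w <- c(-Inf, (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(thr_w, function(t) mean(ws[y] > t), numeric(1))
  fpr <- vapply(thr_w, function(t) mean(ws[!y] > t), numeric(1))
  ord <- order(fpr, sens)
  out <- data.frame(
    threshold = if (higher_is_positive) thr_w[ord] else -thr_w[ord],
    sensitivity = sens[ord], specificity = 1 - fpr[ord],
    tpr = sens[ord], fpr = fpr[ord])
  structure(out, class = c("dwi_roc", "data.frame"),
            auc = max(auc_raw, 1 - auc_raw), positive = positive,
            higher_is_positive = higher_is_positive,
            n_pos = n_pos, n_neg = n_neg)
}

#' @export
print.dwi_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positive = %s, %s scores positive), %d vs %d\n",
              attr(x, "auc"), attr(x, "positive"),
              if (attr(x, "higher_is_positive")) "higher" else "lower",
              attr(x, "n_pos"), attr(x, "n_neg")))
  invisible(x)
}

#' Plot method for ROC curves
#'
#' @param x a `dwi_roc`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dwi_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", attr(x, "auc")))
  invisible(x)
}

#' AUC with confidence interval
#'
#' The AUC itself is the trapezoidal area under [roc_curve()] (identical to
#' the Mann-Whitney concordance statistic with ties counted one half). The
#' 95% confidence interval uses the DeLong variance estimator by default,
#' or the Hanley-McNeil binormal-free approximation with
#' `method = "hanley"`.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` (default) or `"hanley"`.
#' @param conf confidence level.
#' @return List with `auc`, `lower`, `upper`, `method`, `positive`,
#'   `higher_is_positive`.
#' @export
auc_with_ci <- function(scores, labels, positive = NULL,
                        method = c("delong", "hanley"), conf = 0.95) {
  method <- match.arg(method)
  rc <- roc_curve(scores, labels, positive)
  auc <- attr(rc, "auc")
  n_pos <- attr(rc, "n_pos"); n_neg <- attr(rc, "n_neg")
  if (method == "delong") {
    ok <- !is.na(scores) & !is.na(labels)
    y <- factor(labels[ok]) == attr(rc, "positive")
    pr <- pROC::roc(response = y, predictor = as.numeric(scores[ok]),
                    levels = c(FALSE, TRUE),
                    direction = if (attr(rc, "higher_is_positive")) "<" else ">",
                    quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(pr, conf.level = conf, method = "delong"))
    lower <- ci[1]; upper <- ci[3]
  } else {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
    z <- qnorm(1 - (1 - conf) / 2)
    lower <- max(0, auc - z * se); upper <- min(1, auc + z * se)
  }
  list(auc = auc, lower = lower, upper = upper, method = method,
       positive = attr(rc, "positive"),
       higher_is_positive = attr(rc, "higher_is_positive"))
}

#' Youden-index optimal cutoff
#'
#' Scans every threshold of an ROC curve for the maximum of the Youden
#' index J = sensitivity + specificity - 1. Ties are broken toward the
#' higher sensitivity, then toward the lower threshold. A curve whose best
#' J is (numerically) zero carries no discrimination and is flagged
#' degenerate.
#'
#' @param roc a `dwi_roc` from [roc_curve()].
#' @return List with `threshold`, `sensitivity` and `specificity` (percent),
#'   `youden`, and `degenerate`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "dwi_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  jmax <- max(j)
  cand <- which(j >= jmax - 1e-12)
  cand <- cand[roc$sensitivity[cand] >= max(roc$sensitivity[cand]) - 1e-12]
  pick <- cand[which.min(roc$threshold[cand])]
  list(threshold = roc$threshold[pick],
       sensitivity = 100 * roc$sensitivity[pick],
       specificity = 100 * roc$specificity[pick],
       youden = jmax,
       degenerate = jmax <= 1e-12)
}

#' Sensitivity, specificity, PPV and NPV of a binary prediction
#'
#' Standard confusion-matrix ratios in percent, rounded to two decimals.
#' A ratio with a zero denominator (e.g. NPV when nothing is predicted
#' negative) is reported as `NA`, not as 0.
#'
#' @param labels true class labels.
#' @param predictions predicted class labels (same coding).
#' @param positive the positive class (default `"CR"` when present).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (percent)
#'   and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' predictive_values(rep(c("CR", "non-CR"), c(37, 16)),
#'                   rep(c("CR", "non-CR", "CR", "non-CR"), c(31, 6, 4, 12)))
predictive_values <- function(labels, predictions, positive = NULL) {
  labels <- factor(labels); predictions <- factor(predictions, levels(labels))
  if (is.null(positive)) {
    positive <- if ("CR" %in% levels(labels)) "CR" else levels(labels)[1]
  }
  y <- labels == positive; yh <- predictions == positive
  tp <- sum(y & yh); fn <- sum(y & !yh)
  tn <- sum(!y & !yh); fp <- sum(!y & yh)
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 2)
  list(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Per-parameter ROC summary table
#'
#' For each marker column: AUC with confidence interval, Youden-optimal
#' cutoff, and the four predictive values at that cutoff, with the CR group
#' as the positive class.
#'
#' @param cohort data frame with a two-level `group` column and marker
#'   columns.
#' @param parameters marker column names (default: every `_t0`/`_t1`/
#'   `_delta` column).
#' @param positive positive class label (default `"CR"`).
#' @param ci_method forwarded to [auc_with_ci()].
#' @return Data frame with one row per marker: `parameter`, `auc`,
#'   `ci_lower`, `ci_upper`, `cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `direction`.
#' @export
roc_table <- function(cohort, parameters = NULL, positive = "CR",
                      ci_method = "delong") {
  if (is.null(parameters)) {
    parameters <- grep("_(t0|t1|delta)$", names(cohort), value = TRUE)
  }
  rows <- lapply(parameters, function(pn) {
    scores <- cohort[[pn]]
    rc <- roc_curve(scores, cohort$group, positive)
    ci <- auc_with_ci(scores, cohort$group, positive, method = ci_method)
    yc <- youden_cutoff(rc)
    hip <- attr(rc, "higher_is_positive")
    pred <- if (hip) scores > yc$threshold else scores < yc$threshold
    pv <- predictive_values(cohort$group == positive, pred, positive = TRUE)
    data.frame(parameter = pn, auc = ci$auc, ci_lower = ci$lower,
               ci_upper = ci$upper, cutoff = yc$threshold,
               sensitivity = pv$sensitivity, specificity = pv$specificity,
               ppv = pv$ppv, npv = pv$npv,
               direction = if (hip) "higher" else "lower")
  })
  do.call(rbind, rows)
}
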