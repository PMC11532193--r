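#' Replicate-level calibration metrics
#'
#' Summarises a Monte-Carlo batch of `N` replicate fits into the standard
#' calibration metrics, per parameter:
#'
#' * `bias` — mean estimate minus the truth;
#' * `see`  — empirical standard error of the estimates, the sample standard
#'   deviation with `N - 1` denominator;
#' * `sem`  — mean of the per-replicate estimated standard errors (agreement
#'   of `sem` with `see` indicates correctly calibrated uncertainty);
#' * `mse`  — mean squared error about the truth;
#' * `cp`   — coverage probability, the fraction of `level` confidence
#'   intervals containing the truth;
#' * `rejection_rate` — fraction of replicates whose two-sided Wald test at
#'   `alpha = 1 - level` rejects zero (the type I error when the true value
#'   is zero, the power otherwise).
#'
#' Rejection is defined by the `level` interval excluding zero, so for a
#' truth of zero `rejection_rate = 1 - cp` exactly.
#'
#' @param estimates N x p matrix of per-replicate coefficient estimates.
#' @param ses N x p matrix of per-replicate standard errors.
#' @param truth length-p vector of true parameter values.
#' @param level confidence level (default 0.95).
#' @param df degrees of freedom of the interval's t reference; `Inf` for
#'   normal.
#' @return data frame with one row per parameter and columns `parameter`,
#'   `truth`, `bias`, `see`, `sem`, `mse`, `cp`, `rejection_rate`, `n_reps`.
#' @export
summarize_replicates <- function(estimates, ses, truth, level = 0.95,
                                 df = Inf) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  if (!all(dim(estimates) == dim(ses)))
    stop("estimates and ses must have the same dimensions")
  n_reps <- nrow(estimates)
  p <- ncol(estimates)
  if (n_reps < 2L) stop("need at least 2 replicates (SEE undefined for N < 2)")
  if (length(truth) != p) stop("truth must have one entry per parameter")

  q <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df = df) else stats::qnorm(1 - (1 - level) / 2)
  lower <- estimates - q * ses
  upper <- estimates + q * ses
  covers <- sweep(lower, 2L, truth, "<=") & sweep(upper, 2L, truth, ">=")
  rejects <- lower > 0 | upper < 0

  params <- colnames(estimates)
  if (is.null(params)) params <- paste0("beta", seq_len(p) - 1L)
  data.frame(
    parameter = params,
    truth = as.numeric(truth),
    bias = colMeans(estimates) - truth,
    see = apply(estimates, 2L, stats::sd),
    sem = colMeans(ses),
    mse = colMeans(sweep(estimates, 2L, truth, "-")^2),
    cp = colMeans(covers),
    rejection_rate = colMeans(rejects),
    n_reps = n_reps,
    row.names = NULL
  )
}

#' Confusion-matrix summaries for multi-taxon discovery
#'
#' Computes, from true/false positive/negative counts:
#' false discovery rate `FDR = FP / (FP + TP)`, true positive rate
#' `TPR = TP / (FN + TP)`, `F1 = 2 * precision * recall /
#' (precision + recall)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate cases follow the conventions: FDR is 0 when there are no
#' discoveries, TPR is 0 when there are no true signals, F1 is 0 when
#' precision and recall are both 0, and MCC is 0 when any marginal count is
#' zero.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return named list with `fdr`, `tpr`, `f1`, `mcc`.
#' @examples
#' confusion_metrics(tp = 8, fp = 2, tn = 78, fn = 12)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  fdr <- if (tp + fp == 0) 0 else fp / (fp + tp)
  tpr <- if (tp + fn == 0) 0 else tp / (fn + tp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + tpr == 0) 0 else 2 * precision * tpr / (precision + tpr)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  list(fdr = fdr, tpr = tpr, f1 = f1, mcc = mcc)
}
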