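#' Confusion matrix of a binary growth prediction
#'
#' @param predicted,actual logical vectors of equal length (positive =
#'   lesion growth).
#' @return object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual) || !length(predicted))
    stop("predicted and actual must be non-empty and of equal length")
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  structure(list(tp = sum(predicted & actual),
                 fp = sum(predicted & !actual),
                 fn = sum(!predicted & actual),
                 tn = sum(!predicted & !actual)),
            class = "confusion_matrix")
}

# exact (Clopper-Pearson) or Wilson binomial CI, on the percent scale
binom_ci <- function(x, n, conf = 0.95, method = c("clopper_pearson",
                                                   "wilson")) {
  method <- match.arg(method)
  a <- 1 - conf
  if (method == "clopper_pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  c(lower = 100 * lo, upper = 100 * hi)
}

#' Diagnostic performance with exact binomial confidence intervals
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' values (as percentages) with per-metric 95% binomial confidence
#' intervals (Clopper-Pearson by default).  A metric whose denominator
#' is zero is reported as `NA` (undefined), not 0.
#'
#' @param cm a [confusion()] result.
#' @param ci_method `"clopper_pearson"` (exact) or `"wilson"`.
#' @param conf confidence level.
#' @return object of class `diagnostic_metrics`: a data frame with one
#'   row per metric (`estimate`, `lower`, `upper`, in percent).
#' @export
diagnostic_metrics <- function(cm, ci_method = c("clopper_pearson",
                                                 "wilson"),
                               conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix")
  one <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, lower = NA_real_,
                         upper = NA_real_))
    c(estimate = 100 * x / n, binom_ci(x, n, conf, ci_method))
  }
  out <- rbind(sensitivity = one(cm$tp, cm$tp + cm$fn),
               specificity = one(cm$tn, cm$tn + cm$fp),
               accuracy = one(cm$tp + cm$tn, total),
               ppv = one(cm$tp, cm$tp + cm$fp),
               npv = one(cm$tn, cm$tn + cm$fn))
  out <- as.data.frame(out)
  out$metric <- rownames(out)
  rownames(out) <- NULL
  structure(out[, c("metric", "estimate", "lower", "upper")],
            class = c("diagnostic_metrics", "data.frame"))
}

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' Given rates printed to one decimal place and the group sizes, the
#' underlying integer counts are recovered by rounding
#' (`tp = round(sens * n_pos / 100)`, `tn = round(spec * n_neg / 100)`)
#' and the full metric set is recomputed from those counts.
#'
#' @param sensitivity_pct,specificity_pct printed rates in percent.
#' @param n_pos,n_neg numbers of outcome-positive and -negative cases.
#' @param ci_method passed to [diagnostic_metrics()].
#' @return list with `cm` (a `confusion_matrix`) and `metrics` (a
#'   `diagnostic_metrics`).
#' @export
metrics_from_rates <- function(sensitivity_pct, specificity_pct,
                               n_pos, n_neg,
                               ci_method = "clopper_pearson") {
  stopifnot(sensitivity_pct >= 0, sensitivity_pct <= 100,
            specificity_pct >= 0, specificity_pct <= 100,
            n_pos >= 1, n_neg >= 1)
  tp <- round(sensitivity_pct * n_pos / 100)
  tn <- round(specificity_pct * n_neg / 100)
  if (tp < 0 || tp > n_pos || tn < 0 || tn > n_neg)
    stop("reconstructed counts fall outside the group sizes")
  cm <- structure(list(tp = tp, fp = n_neg - tn, fn = n_pos - tp,
                       tn = tn),
                  class = "confusion_matrix")
  list(cm = cm, metrics = diagnostic_metrics(cm, ci_method))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> tp", x$tp, "fp", x$fp, "fn", x$fn, "tn",
      x$tn, "\n")
  invisible(x)
}
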