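#' Confusion matrix over ordered class labels
#'
#' @param truth,predicted Character vectors of class labels.
#' @param labels Ordered label set (default: sorted union).
#' @return An integer matrix (rows = truth, columns = predicted).
#' @export
confusion_matrix <- function(truth, predicted,
                             labels = sort(unique(c(truth, predicted)))) {
  stopifnot(length(truth) == length(predicted))
  t_f <- factor(truth, levels = labels)
  p_f <- factor(predicted, levels = labels)
  as.matrix(table(truth = t_f, predicted = p_f))
}

#' Binomial proportion with confidence interval
#'
#' Computes a point estimate with either the Wilson score interval
#' (inverting the score test) or the Wald normal approximation
#' (`p +/- z * sqrt(p(1-p)/n)`, clipped to `[0, 1]`).  Both are
#' provided because validation reports in this field use either; the
#' returned object records which was used.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param method `"wilson"` or `"wald"`.
#' @param level Confidence level (default 0.95).
#' @return A list of class `accuracy_report`: `n`, `successes`,
#'   `estimate`, `method`, `lower`, `upper`.
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "wald"),
                          level = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm((1 + level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lower <- max(0, p - half)
    upper <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- if (successes == 0) 0 else max(0, centre - half)
    upper <- if (successes == n) 1 else min(1, centre + half)
  }
  structure(list(n = n, successes = successes, estimate = p,
                 method = method, lower = lower, upper = upper),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f (%s 95%% CI %.4f to %.4f)\n",
              x$successes, x$n, x$estimate, x$method, x$lower, x$upper))
  invisible(x)
}

#' Prevalence-weighted g-means over a confusion matrix
#'
#' For each class `i` (one-vs-rest), `g_i = sqrt(recall_i *
#' specificity_i)`; the statistic is the prevalence-weighted sum
#' `sum(w_i * g_i)` over classes with at least one true instance
#' (weights renormalised over those classes).  Robust to class
#' imbalance: a majority class cannot mask collapsed minority recall.
#'
#' @param cm Confusion matrix (rows = truth, columns = predicted).
#' @return Value in `[0, 1]`.
#' @export
weighted_gmeans <- function(cm) {
  if (length(cm) == 0 || sum(cm) == 0) stop("empty confusion matrix")
  n <- sum(cm)
  true_tot <- rowSums(cm)
  pred_tot <- colSums(cm)
  keep <- true_tot > 0
  tp <- diag(cm)
  recall <- ifelse(true_tot > 0, tp / true_tot, NA_real_)
  tn <- n - true_tot - pred_tot + tp
  specificity <- tn / (n - true_tot)
  g <- sqrt(recall * specificity)
  w <- true_tot[keep] / sum(true_tot[keep])
  sum(w * g[keep])
}

#' Overall accuracy of the two-stage dosage prediction
#'
#' One minus the fraction of erroneous predictions among the
#' prescriptions the pipeline classified as informative: an error is a
#' predicted pills/day differing from the gold pills/day, and a
#' gold-non-informative prescription classified informative also counts
#' as an error.  The all-prescription variant (denominator = all
#' entries, counting stage-1 agreement on non-informativeness as
#' correct) is reported for audit.
#'
#' @param predicted_pills Final predicted pills/day (`NA` where the
#'   pipeline classified the text non-informative).
#' @param gold_informative Logical gold informativeness.
#' @param gold_pills Gold pills/day (`NA` where non-informative).
#' @return A list with `informative` (an `accuracy_report` over the
#'   informative-classified denominator, or `NULL` when that
#'   denominator is empty) and `all` (accuracy over all entries).
#' @export
overall_accuracy <- function(predicted_pills, gold_informative, gold_pills) {
  stopifnot(length(predicted_pills) == length(gold_informative),
            length(gold_pills) == length(gold_informative))
  classified_inf <- !is.na(predicted_pills)
  n_inf <- sum(classified_inf)
  inf_report <- NULL
  if (n_inf > 0) {
    correct <- classified_inf & gold_informative &
      !is.na(gold_pills) & abs(predicted_pills - gold_pills) < 1e-9
    inf_report <- proportion_ci(sum(correct, na.rm = TRUE), n_inf,
                                method = "wald")
  }
  agree_noninf <- !classified_inf & !gold_informative
  correct_all <- sum(agree_noninf) +
    sum(classified_inf & gold_informative & !is.na(gold_pills) &
          abs(predicted_pills - ifelse(is.na(gold_pills), Inf, gold_pills))
        < 1e-9)
  list(informative = inf_report,
       all = proportion_ci(correct_all, length(predicted_pills),
                           method = "wald"))
}

#' Cross-tabulate prediction errors by relative size and gold class
#'
#' Relative error `|pred - gold| / gold`; exact predictions are not
#' errors and are excluded.  Bins: `(0, 0.2]`, `(0.2, 0.5]`,
#' `(0.5, Inf)` — i.e. <=20%, 20-50% and >50%.
#'
#' @param predicted_pills,gold_pills Numeric pills/day (gold > 0).
#' @param codec Dosage codec (rows of the output table).
#' @return Integer matrix: gold dosage class x error-size bin.
#' @export
error_size_bins <- function(predicted_pills, gold_pills,
                            codec = dosage_codec()) {
  stopifnot(length(predicted_pills) == length(gold_pills),
            all(gold_pills > 0, na.rm = TRUE))
  rel <- abs(predicted_pills - gold_pills) / gold_pills
  err <- which(!is.na(rel) & rel > 1e-12)
  bin <- cut(rel[err], breaks = c(0, 0.2, 0.5, Inf),
             labels = c("<=20%", "20-50%", ">50%"), right = TRUE)
  cls <- factor(pills_to_class(gold_pills[err], codec),
                levels = codec$labels)
  as.matrix(table(class = cls, bin = bin))
}
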