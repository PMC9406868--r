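#' One-way ANOVA
#'
#' Standard between/within mean-square F test with `(k-1, N-k)` degrees of
#' freedom.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `F`, `p_value`, `df`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) .stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    .stop("each group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- stats::oneway.test(y ~ g, var.equal = TRUE)
  if (!is.finite(res$statistic))
    .stop("degenerate ANOVA (zero within-group variance)")
  list(F = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Spearman or Pearson correlation with test
#'
#' Spearman is Pearson on midranks, with p-value from the t approximation;
#' Pearson uses the exact t reference distribution.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r` and `p_value`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) .stop("x and y must have equal length")
  if (length(x) < 3) .stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stop("constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return A `km_curve` data frame with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `survival`.  Censored-only data gives zero
#'   rows (survival constant 1).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) .stop("need at least one subject")
  if (anyNA(times) || any(times < 0)) .stop("times must be non-negative")
  if (anyNA(events) || !all(events %in% 0:1)) .stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], survival = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  attr(out, "n") <- length(times)
  out
}

#' Log-rank test across survival groups
#'
#' Observed-minus-expected statistic with hypergeometric variance, referred
#' to a chi-squared distribution with `g - 1` degrees of freedom.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators.
#' @param groups Group labels (>= 2 groups, each >= 1 subject).
#' @return List with `chi2`, `p_value`, `df`.
#' @export
logrank_test <- function(times, events, groups) {
  if (anyNA(times) || any(times < 0)) .stop("times must be non-negative")
  if (anyNA(events) || !all(events %in% 0:1)) .stop("events must be 0/1")
  g <- factor(groups)
  if (nlevels(g) < 2) .stop("need at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  list(chi2 = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all observed thresholds with trapezoidal AUC; ties are
#' handled so that the AUC equals the tie-corrected rank statistic
#' `U / (n1 * n0)`.  The default risk direction is `"low_is_positive"`
#' (metastatic tumors carry *lower* m6A scores).
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (1/TRUE = positive class); both classes must
#'   be present.
#' @param risk_direction `"low_is_positive"` (default) or
#'   `"high_is_positive"`.
#' @return A `roc_curve` list: `auc`, `thresholds`, `sensitivity`,
#'   `specificity`, `risk_direction`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), "high_is_positive")$auc  # 0.75
#' @export
roc_auc <- function(scores, labels,
                    risk_direction = c("low_is_positive", "high_is_positive")) {
  risk_direction <- match.arg(risk_direction)
  lab <- as.integer(as.logical(labels))
  if (anyNA(lab) || anyNA(scores)) .stop("missing values not allowed")
  if (length(unique(lab)) < 2) .stop("both classes must be present")
  ## pROC direction "<": controls have lower scores than cases
  dir <- if (risk_direction == "high_is_positive") "<" else ">"
  r <- pROC::roc(response = lab, predictor = as.numeric(scores),
                 levels = c("0", "1"), direction = dir, quiet = TRUE)
  structure(list(auc = as.numeric(r$auc),
                 thresholds = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities,
                 risk_direction = risk_direction,
                 n_pos = sum(lab == 1), n_neg = sum(lab == 0)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive / %d negative, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$risk_direction))
  invisible(x)
}

#' Rank-based stemness index
#'
#' Each sample's raw index is the Spearman correlation between a supplied
#' stemness signature weight vector and the sample's expression over the
#' overlapping genes; the raw indices are then min-max scaled to `[0, 1]`
#' across the cohort (subtract the minimum, divide by the range).
#'
#' @param m Expression matrix with >= 2 samples.
#' @param weights Named numeric signature weights; >= 3 genes must overlap
#'   the matrix rows.
#' @return Data frame with `sample_id`, `raw_index`, `stemness_index`.
#' @export
stemness_index <- function(m, weights) {
  validate_expression_matrix(m)
  if (ncol(m) < 2) .stop("need at least 2 samples")
  if (is.null(names(weights))) .stop("weights must be named by gene id")
  ov <- intersect(names(weights), rownames(m))
  if (length(ov) < 3) .stop("fewer than 3 genes overlap the weight vector")
  w <- weights[ov]
  raw <- apply(m[ov, , drop = FALSE], 2,
               function(e) stats::cor(w, e, method = "spearman"))
  rng <- range(raw)
  if (diff(rng) <= 0) .stop("stemness index is constant across the cohort")
  data.frame(sample_id = colnames(m), raw_index = unname(raw),
             stemness_index = unname((raw - rng[1]) / diff(rng)),
             stringsAsFactors = FALSE, row.names = NULL)
}
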