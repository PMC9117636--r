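#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit estimator per group and the unweighted two-sided log-rank
#' statistic (observed minus expected event counts over the pooled event
#' times, hypergeometric variance), with a chi-square p-value on
#' `groups - 1` degrees of freedom.
#'
#' @param os_time Positive survival/censoring times.
#' @param os_event Event indicators (1 = death observed).
#' @param groups Group labels (>= 2 distinct values).
#' @return List of class `km_result`: `curves` (per-group data.frame of
#'   time, n_risk, n_event, surv), `logrank_chi2`, `logrank_p`, `df`.
#' @export
km_logrank <- function(os_time, os_event, groups) {
  ok <- !is.na(os_time) & !is.na(os_event) & !is.na(groups)
  os_time <- os_time[ok]; os_event <- os_event[ok]; groups <- groups[ok]
  if (any(os_time <= 0)) stop_arg("all times must be > 0")
  if (length(unique(groups)) < 2) stop_arg("need >= 2 groups")
  g <- factor(groups)
  sd_fit <- survival::survdiff(survival::Surv(os_time, os_event) ~ g)
  df <- length(levels(g)) - 1L
  chi2 <- sd_fit$chisq
  curves <- lapply(levels(g), function(lv) {
    f <- survival::survfit(survival::Surv(os_time[g == lv],
                                          os_event[g == lv]) ~ 1)
    data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
               surv = f$surv)
  })
  names(curves) <- levels(g)
  structure(list(curves = curves, logrank_chi2 = chi2,
                 logrank_p = pchisq(chi2, df, lower.tail = FALSE), df = df),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("km_result: %d groups, log-rank chi2 = %.3f (df = %d), p = %.3g\n",
              length(x$curves), x$logrank_chi2, x$df, x$logrank_p))
  invisible(x)
}

#' Empirical ROC and AUC of a score against binary labels
#'
#' ROC over all score thresholds with trapezoidal AUC; with tied scores
#' the trapezoid rule reproduces the midrank Mann-Whitney identity
#' `AUC = U / (n1 * n0)`.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels (logical, or 0/1, or two-level factor whose
#'   second level is positive).
#' @return List of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
score_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop_arg("both label classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # cumulative counts at each distinct threshold (descending)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  thresholds <- s[last_of_tie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, thresholds), tpr = tpr, fpr = fpr,
                 auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Lower-quartile response contrast
#'
#' Splits samples at the lower quartile (Q1, type-7 quantile) of the
#' scores — `low` = scores <= Q1, `high` = the rest — and contrasts the
#' responder rates with a two-sided exact test on the 2x2 table. This is
#' the immunotherapy-response read-out of the EMD score (low scores are
#' expected to respond more).
#'
#' @param scores Numeric scores.
#' @param responses `responder` / `non_responder` labels (or logical).
#' @return List: `rate_high`, `rate_low` (responder fractions), `n_high`,
#'   `n_low`, `fisher_p`, `table`.
#' @export
response_contrast <- function(scores, responses) {
  ok <- !is.na(scores) & !is.na(responses)
  scores <- scores[ok]; responses <- responses[ok]
  if (length(scores) < 4) stop_arg("need >= 4 samples")
  if (is.character(responses)) responses <- responses == "responder"
  responses <- as.logical(responses)
  q1 <- quantile(scores, 0.25, type = 7, names = FALSE)
  low <- scores <= q1
  if (!any(low) || all(low)) stop_arg("empty group after Q1 split")
  tab <- matrix(c(sum(responses[low]), sum(!responses[low]),
                  sum(responses[!low]), sum(!responses[!low])),
                nrow = 2,
                dimnames = list(c("responder", "non_responder"),
                                c("low", "high")))
  list(rate_high = mean(responses[!low]), rate_low = mean(responses[low]),
       n_high = sum(!low), n_low = sum(low),
       fisher_p = fisher.test(tab)$p.value, table = tab)
}
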