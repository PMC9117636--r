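get_values <- function(x) {
  if (inherits(x, "expr_dataset")) x$values
  else if (is.matrix(x)) x
  else stop_arg("expected an expr_dataset or a matrix")
}

#' Differential expression between two sample groups
#'
#' Per-gene Welch unequal-variance t-test on log2-scale values;
#' `log2fc = mean(group_a) - mean(group_b)`. Benjamini-Hochberg adjustment
#' over all tested genes. A record is returned for every gene with a
#' `passes` flag for the study thresholds `|log2fc| > 1` and `p < 0.05`.
#' Genes with zero variance in both groups and equal means get `p = 1` by
#' convention.
#'
#' @param x An [expr_dataset()] or genes x samples matrix.
#' @param group_a,group_b Disjoint sample-id vectors, each of size >= 3.
#' @return data.frame(gene_id, log2fc, p_value, p_adj, passes).
#' @export
differential_expression <- function(x, group_a, group_b) {
  values <- get_values(x)
  if (length(intersect(group_a, group_b))) stop_arg("groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop_arg("each group needs >= 3 samples")
  }
  miss <- setdiff(c(group_a, group_b), colnames(values))
  if (length(miss)) stop_arg("unknown sample(s): %s", paste(miss, collapse = ", "))
  a <- values[, group_a, drop = FALSE]
  b <- values[, group_b, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  log2fc <- m1 - m2
  tstat <- log2fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(log2fc[zero] == 0, 1, 0)
  out <- data.frame(gene_id = rownames(values), log2fc = log2fc,
                    p_value = p, p_adj = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$passes <- abs(out$log2fc) > 1 & out$p_value < 0.05
  rownames(out) <- NULL
  out
}

# Spearman correlations of target rows against regulator rows, with
# t-approximation p-values; constant rows are dropped with a warning.
spearman_pairs <- function(values, targets, regulators_ids) {
  n <- ncol(values)
  keep_ok <- function(ids) {
    ok <- ids[apply(values[ids, , drop = FALSE], 1, sd) > 0]
    if (length(ok) < length(ids)) {
      warning(sprintf("dropping constant gene(s): %s",
                      paste(setdiff(ids, ok), collapse = ", ")), call. = FALSE)
    }
    ok
  }
  targets <- keep_ok(intersect(targets, rownames(values)))
  regulators_ids <- keep_ok(intersect(regulators_ids, rownames(values)))
  rt <- t(apply(values[targets, , drop = FALSE], 1, rank))
  rr <- t(apply(values[regulators_ids, , drop = FALSE], 1, rank))
  rho <- cor(t(rt), t(rr))
  long <- data.frame(
    gene_id = rep(targets, times = length(regulators_ids)),
    regulator_id = rep(regulators_ids, each = length(targets)),
    rho = as.vector(rho), stringsAsFactors = FALSE
  )
  tstat <- long$rho * sqrt((n - 2) / pmax(1 - long$rho^2, .Machine$double.eps))
  long$p_value <- 2 * pt(-abs(tstat), n - 2)
  long
}

#' Correlate candidate genes with the m6A regulators (CEG screen)
#'
#' Spearman correlation of each target gene with each m6A regulator
#' present in the matrix, BH-adjusted over all pairs. A pair is flagged
#' `sig` when `|rho| > rho_threshold` and adjusted p < 0.05; a gene is a
#' correlatively expressed gene (CEG) when any of its m6A-regulator pairs
#' is flagged.
#'
#' @param x An [expr_dataset()] or matrix (>= 10 samples).
#' @param targets Candidate gene ids.
#' @param regulators Regulator table as from [default_regulators()].
#' @param rho_threshold Absolute correlation threshold (default 0.3).
#' @return data.frame(gene_id, regulator_id, role, rho, p_value, p_adj, sig).
#' @export
correlate_with_regulators <- function(x, targets,
                                      regulators = default_regulators(),
                                      rho_threshold = 0.3) {
  values <- get_values(x)
  if (ncol(values) < 10) stop_arg("need >= 10 samples")
  m6a <- m6a_regulators(regulators)
  long <- spearman_pairs(values, setdiff(targets, m6a$regulator_id),
                         m6a$regulator_id)
  long$role <- m6a$role[match(long$regulator_id, m6a$regulator_id)]
  long$p_adj <- p.adjust(long$p_value, "BH")
  long$sig <- abs(long$rho) > rho_threshold & long$p_adj < 0.05
  long[, c("gene_id", "regulator_id", "role", "rho", "p_value", "p_adj", "sig")]
}

#' CEG gene ids from a correlation table
#' @param records Output of [correlate_with_regulators()].
#' @return Character vector of genes with at least one flagged pair.
#' @export
ceg_genes <- function(records) sort(unique(records$gene_id[records$sig]))

#' Pairwise co-expression of the epigenetic regulators
#'
#' Spearman correlation over all unordered regulator pairs present in the
#' matrix; a pair is flagged at `|rho| > 0.3` and unadjusted p < 0.05
#' (BH-adjusted values are also reported).
#'
#' @inheritParams correlate_with_regulators
#' @return data.frame(gene_a, gene_b, rho, p_value, p_adj, sig).
#' @export
regulator_coexpression <- function(x, regulators = default_regulators(),
                                   rho_threshold = 0.3) {
  values <- get_values(x)
  ids <- intersect(regulators$regulator_id, rownames(values))
  long <- spearman_pairs(values, ids, ids)
  keep <- match(long$gene_id, ids) < match(long$regulator_id, ids)
  long <- long[keep, , drop = FALSE]
  names(long)[1:2] <- c("gene_a", "gene_b")
  long$p_adj <- p.adjust(long$p_value, "BH")
  long$sig <- abs(long$rho) > rho_threshold & long$p_value < 0.05
  rownames(long) <- NULL
  long
}

#' Pairwise mutation co-occurrence / mutual-exclusivity test
#'
#' For every unordered gene pair, builds the 2x2 presence/absence table
#' across samples and applies the exact conditional (hypergeometric-based)
#' two-sided test. Direction is `co_occurrence` when the observed joint
#' count exceeds its expectation under independence, otherwise
#' `mutual_exclusivity`. Pairs flagged at p < 0.05 are the co-mutation
#' events. Genes mutated in no or all samples give a degenerate record
#' with p = 1.
#'
#' @param mutations Binary samples x genes matrix.
#' @param genes Gene columns to test (default: all).
#' @param adjust Also compute BH-adjusted p-values over the pairs.
#' @return data.frame(gene_a, gene_b, n11, n10, n01, n00, odds_ratio,
#'   p_value, direction, degenerate \[, p_adj\]).
#' @export
comutation_test <- function(mutations, genes = colnames(mutations),
                            adjust = FALSE) {
  if (length(genes) < 2) stop_arg("need >= 2 genes")
  if (nrow(mutations) < 1) stop_arg("need >= 1 sample")
  miss <- setdiff(genes, colnames(mutations))
  if (length(miss)) stop_arg("unknown gene(s): %s", paste(miss, collapse = ", "))
  n <- nrow(mutations)
  pairs <- utils::combn(genes, 2)
  out <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    a <- mutations[, ga]; b <- mutations[, gb]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    degen <- (n11 + n10) %in% c(0L, n) || (n11 + n01) %in% c(0L, n)
    if (degen) {
      p <- 1
    } else {
      p <- fisher.test(matrix(c(n11, n01, n10, n00), 2))$p.value
    }
    expected <- (n11 + n10) * (n11 + n01) / n
    orat <- if (n10 * n01 == 0) {
      if (n11 * n00 == 0) NA_real_ else Inf
    } else n11 * n00 / (n10 * n01)
    out[[i]] <- data.frame(
      gene_a = ga, gene_b = gb, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
      odds_ratio = orat, p_value = p,
      direction = if (n11 > expected) "co_occurrence" else "mutual_exclusivity",
      degenerate = degen, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (adjust) res$p_adj <- p.adjust(res$p_value, "BH")
  res
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits one proportional-hazards model per candidate gene (Breslow tie
#' handling) against overall survival and flags genes with Wald p below
#' `alpha` (the survival-associated screen uses `alpha = 0.01`).
#' Constant-expression candidates are excluded with a warning;
#' non-converging fits are reported with `converged = FALSE` and
#' `passes = FALSE`.
#'
#' @param x An [expr_dataset()] with `os_time`/`os_event` in `samples`, or
#'   a matrix plus explicit `os_time`, `os_event` vectors.
#' @param candidates Gene ids to screen.
#' @param alpha Wald p-value threshold (default 0.01).
#' @param os_time,os_event Survival fields when `x` is a bare matrix.
#' @return data.frame(gene_id, coef, se, p_value, passes, converged).
#' @export
cox_screen <- function(x, candidates, alpha = 0.01,
                       os_time = NULL, os_event = NULL) {
  values <- get_values(x)
  if (inherits(x, "expr_dataset")) {
    os_time <- os_time %||% x$samples$os_time
    os_event <- os_event %||% x$samples$os_event
  }
  ok <- !is.na(os_time) & !is.na(os_event)
  if (sum(ok) < 30) stop_arg("need os_time/os_event for >= 30 samples")
  values <- values[, ok, drop = FALSE]
  surv <- survival::Surv(os_time[ok], os_event[ok])
  candidates <- intersect(candidates, rownames(values))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    g <- candidates[i]
    xg <- values[g, ]
    if (sd(xg) == 0) {
      warning(sprintf("candidate %s has constant expression; excluded", g),
              call. = FALSE)
      next
    }
    fit <- tryCatch(
      survival::coxph(surv ~ xg, ties = "breslow"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(surv ~ xg, ties = "breslow"))
      })
    if (is.null(fit)) {
      rows[[i]] <- data.frame(gene_id = g, coef = NA_real_, se = NA_real_,
                              p_value = NA_real_, passes = FALSE,
                              converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    sm <- summary(fit)$coefficients
    converged <- is.finite(sm[1, "coef"]) && is.finite(sm[1, "se(coef)"]) &&
      abs(sm[1, "coef"]) < 50
    p <- sm[1, "Pr(>|z|)"]
    rows[[i]] <- data.frame(gene_id = g, coef = sm[1, "coef"],
                            se = sm[1, "se(coef)"], p_value = p,
                            passes = converged && !is.na(p) && p < alpha,
                            converged = converged, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
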