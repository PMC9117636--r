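#' Select the EMD up/down signature (set1/set2)
#'
#' Simplified module/trait-correlation selection over the DEGs between the
#' EMD and reference clusters. Passing DEGs are partitioned by the sign of
#' their gene significance GS (Pearson correlation of the gene's expression
#' with the binary EMD indicator); each sign group's first principal
#' eigen-profile (a module-eigengene surrogate, oriented towards its member
#' genes) defines module membership MM (correlation of each gene with the
#' eigen-profile). `set1` is the positive-GS genes with `GS >= gs_threshold`
#' and `MM >= mm_threshold`; `set2` symmetrically for negative GS.
#'
#' @param x An [expr_dataset()] or matrix.
#' @param deg DEG table from [differential_expression()] (EMD vs reference).
#' @param emd_samples Sample ids of the EMD cluster.
#' @param gs_threshold Minimum |GS| (default 0.4).
#' @param mm_threshold Minimum MM (default 0.7).
#' @return List of class `emd_signature`: `set1`, `set2`, `table`
#'   (gene_id, gs, mm, set), `selection_params`.
#' @export
select_signature <- function(x, deg, emd_samples,
                             gs_threshold = 0.4, mm_threshold = 0.7) {
  values <- get_values(x)
  passing <- deg$gene_id[deg$passes]
  passing <- intersect(passing, rownames(values))
  if (!length(passing)) stop_arg("no passing DEGs to select from")
  indicator <- as.numeric(colnames(values) %in% emd_samples)
  if (all(indicator == 0) || all(indicator == 1)) {
    stop_arg("emd_samples must be a proper subset of the samples")
  }
  sub <- values[passing, , drop = FALSE]
  keep <- apply(sub, 1, sd) > 0
  sub <- sub[keep, , drop = FALSE]
  gs <- as.vector(cor(t(sub), indicator))
  names(gs) <- rownames(sub)
  module_mm <- function(ids) {
    if (!length(ids)) return(numeric(0))
    zm <- t(scale(t(values[ids, , drop = FALSE])))
    if (length(ids) == 1) {
      return(setNames(1, ids))  # a single gene is its own eigen-profile
    }
    pc <- prcomp(t(zm), center = FALSE, scale. = FALSE)
    eig <- pc$x[, 1]
    mm <- as.vector(cor(t(values[ids, , drop = FALSE]), eig))
    if (mean(mm) < 0) mm <- -mm  # orient towards the module's members
    setNames(mm, ids)
  }
  pos <- names(gs)[gs > 0]
  neg <- names(gs)[gs < 0]
  mm_pos <- module_mm(pos)
  mm_neg <- module_mm(neg)
  set1 <- pos[gs[pos] >= gs_threshold & mm_pos[pos] >= mm_threshold]
  set2 <- neg[gs[neg] <= -gs_threshold & mm_neg[neg] >= mm_threshold]
  if (!length(set1) || !length(set2)) {
    stop_arg(paste("signature selection left an empty set;",
                   "relax gs_threshold/mm_threshold"))
  }
  tab <- data.frame(
    gene_id = c(pos, neg),
    gs = c(gs[pos], gs[neg]),
    mm = c(mm_pos[pos], mm_neg[neg]),
    set = c(ifelse(pos %in% set1, "set1", "none"),
            ifelse(neg %in% set2, "set2", "none")),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(set1 = sort(set1), set2 = sort(set2), table = tab,
                 selection_params = list(gs_threshold = gs_threshold,
                                         mm_threshold = mm_threshold)),
            class = "emd_signature")
}

#' @export
print.emd_signature <- function(x, ...) {
  cat(sprintf("emd_signature: %d set1 (up), %d set2 (down) genes\n",
              length(x$set1), length(x$set2)))
  invisible(x)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-weighted running-sum enrichment of one gene set in one sample's
#' expression profile. Genes are ordered by decreasing expression (ties
#' broken by gene identifier); in-set steps are the rank weights
#' `rank^alpha` normalized to sum to 1 over the set (rank N = highest
#' expression), out-of-set steps are `1/(N - |S|)`, and the score is the
#' integrated running sum (the sum of the in-set minus out-of-set
#' cumulative difference over all positions).
#'
#' @param expr Named numeric vector of one sample's expression.
#' @param gene_set Character vector of gene ids (non-empty intersection
#'   with `names(expr)`, but not all genes).
#' @param alpha Rank-weight exponent (default 0.25).
#' @return The enrichment score (real; positive when the set concentrates
#'   at the top of the profile).
#' @export
ssgsea <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stop_arg("expr must be a named vector")
  inset <- names(expr) %in% gene_set
  n <- length(expr)
  ns <- sum(inset)
  if (ns == 0 || ns == n) stop_arg("gene set must be a non-empty proper subset")
  ord <- order(-expr, names(expr))
  inset <- inset[ord]
  # rank weights: N for the top-ranked gene down to 1
  rk <- seq.int(n, 1)
  w <- rk^alpha * inset
  cum_in <- cumsum(w) / sum(w)
  cum_out <- cumsum(!inset) / (n - ns)
  sum(cum_in - cum_out)
}

#' EMD score per sample
#'
#' Computes the two single-sample enrichment scores (set1 up-signature,
#' set2 down-signature) per sample, min-max rescales each score vector
#' within cohort to (eps, 1] (enrichment scores can be negative, which
#' would leave the log-ratio undefined), and returns
#' `emd_score = log2(rescaled1 / rescaled2)` with a cohort-median high/low
#' split (median-equal samples go to `low`).
#'
#' @param x An [expr_dataset()] (cohort taken from `samples`) or matrix
#'   (single cohort assumed).
#' @param signature An [select_signature()] result, or any list with
#'   `set1`/`set2`.
#' @param alpha Rank-weight exponent passed to [ssgsea()].
#' @param rescale `"cohort"` (default) or `"global"`.
#' @param eps Rescale floor (default 0.01).
#' @return data.frame(sample_id, cohort, ssgsea1, ssgsea2, emd_score,
#'   score_group).
#' @export
emd_score <- function(x, signature, alpha = 0.25,
                      rescale = c("cohort", "global"), eps = 0.01) {
  rescale <- match.arg(rescale)
  values <- get_values(x)
  cohort <- if (inherits(x, "expr_dataset")) x$samples$cohort
            else rep("all", ncol(values))
  s1 <- apply(values, 2, ssgsea, gene_set = signature$set1, alpha = alpha)
  s2 <- apply(values, 2, ssgsea, gene_set = signature$set2, alpha = alpha)
  groups <- if (rescale == "cohort") cohort else rep("all", length(cohort))
  minmax <- function(v) {
    if (length(v) < 2) {
      stop_arg("cohort with a single sample; use rescale = \"global\"")
    }
    if (max(v) == min(v)) return(rep(1, length(v)))
    eps + (1 - eps) * (v - min(v)) / (max(v) - min(v))
  }
  r1 <- r2 <- numeric(length(s1))
  for (g in unique(groups)) {
    i <- groups == g
    r1[i] <- minmax(s1[i])
    r2[i] <- minmax(s2[i])
  }
  score <- log2(r1 / r2)
  grp <- character(length(score))
  for (g in unique(cohort)) {
    i <- cohort == g
    grp[i] <- ifelse(score[i] > median(score[i]), "high", "low")
  }
  data.frame(sample_id = colnames(values), cohort = cohort,
             ssgsea1 = s1, ssgsea2 = s2, emd_score = score,
             score_group = grp, stringsAsFactors = FALSE, row.names = NULL)
}

#' FTO/HDAC1 expression ratio
#'
#' Per-sample contrast of the m6A eraser FTO and the histone deacetylase
#' HDAC1. On the package's log2-scale matrices this is the difference
#' `expr(FTO) - expr(HDAC1)`, i.e. the log2 of the linear-scale ratio;
#' `linear = TRUE` divides the linear-scale values instead.
#'
#' @param x An [expr_dataset()] or matrix containing FTO and HDAC1 rows.
#' @param linear Return the linear-scale ratio `2^FTO / 2^HDAC1`.
#' @return Named numeric vector per sample.
#' @export
fto_hdac1_ratio <- function(x, linear = FALSE) {
  values <- get_values(x)
  for (g in c("FTO", "HDAC1")) {
    if (!g %in% rownames(values)) stop_arg("gene %s missing from matrix", g)
  }
  d <- values["FTO", ] - values["HDAC1", ]
  if (linear) 2^d else d
}
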