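# shared fixture builders and independent oracles

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# a tiny hand-built annotation: genes spaced 50 kb apart on chrT
toy_genes <- function(n = 3, biotype = NULL, strand = NULL) {
  if (is.null(biotype)) {
    biotype <- rep_len(c("protein_coding", "protein_coding", "lncRNA"), n)
  }
  if (is.null(strand)) strand <- rep_len(c("+", "-"), n)
  start <- 10000L + (seq_len(n) - 1L) * 50000L
  end <- start + 6000L
  genes <- data.frame(
    gene_id = sprintf("T%02d", seq_len(n)), biotype = biotype,
    chrom = "chrT", start = start, end = end, strand = strand,
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(strand == "-", end - 1L, start)
  genes$exons <- lapply(seq_len(n), function(i) {
    data.frame(start = c(start[i], end[i] - 1500L),
               end = c(start[i] + 1000L, end[i]))
  })
  genes$cds <- lapply(seq_len(n), function(i) {
    if (biotype[i] == "protein_coding") {
      data.frame(start = start[i] + 100L, end = start[i] + 1000L)
    } else data.frame(start = integer(0), end = integer(0))
  })
  genes$utr3 <- lapply(seq_len(n), function(i) {
    if (biotype[i] == "protein_coding") {
      data.frame(start = end[i] - 300L, end = end[i])
    } else data.frame(start = integer(0), end = integer(0))
  })
  gene_annotation(genes)
}

# brute-force per-base region labeler (independent of classify_site_region)
oracle_region <- function(chrom, s, e, gene, window = 3000L) {
  if (chrom != gene$chrom) return("distal")
  bases <- seq.int(s, e - 1L)
  tss <- gene$tss
  prom <- bases[bases >= tss - window & bases < tss + window]
  if (length(prom)) {
    d <- min(abs(prom - tss))
    if (d < 1000) return("promoter_lt1kb")
    if (d < 2000) return("promoter_1to2kb")
    return("promoter_2to3kb")
  }
  hit <- function(parts) {
    nrow(parts) > 0 &&
      any(vapply(bases, function(b)
        any(b >= parts$start & b < parts$end), logical(1)))
  }
  if (hit(gene$utr3[[1]])) return("utr3")
  if (hit(gene$cds[[1]])) return("cds")
  if (hit(gene$exons[[1]])) return("exon")
  if (any(bases >= gene$start & bases < gene$end)) return("intron")
  "distal"
}

# independently coded step-by-step running-sum enrichment oracle
oracle_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  n <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  genes_sorted <- names(expr)[ord]
  in_set <- genes_sorted %in% gene_set
  ns <- sum(in_set)
  wsum <- 0
  for (i in seq_len(n)) if (in_set[i]) wsum <- wsum + (n - i + 1)^alpha
  score <- 0; cin <- 0; cout <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cin <- cin + (n - i + 1)^alpha / wsum
    else cout <- cout + 1 / (n - ns)
    score <- score + (cin - cout)
  }
  score
}

# full-enumeration two-sided hypergeometric test (fisher.test's rule,
# rebuilt from the definition)
oracle_fisher2x2 <- function(n11, n10, n01, n00) {
  m <- n11 + n10        # mutated in gene A
  k <- n11 + n01        # mutated in gene B
  n <- n11 + n10 + n01 + n00
  support <- max(0, k + m - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n - m, k - x) / choose(n, k), numeric(1))
  obs <- probs[match(n11, support)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# hand-enumeration of the unweighted log-rank statistic for two groups
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    oe <- oe + d1 - e1
  }
  list(chi2 = oe^2 / v, oe = oe, v = v)
}

# literal application of the two gene-definition rules, as a triple loop
oracle_criterion1 <- function(dhms, deg, genes, window = 3000L) {
  found <- character(0)
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, , drop = FALSE]
    for (s in seq_len(nrow(dhms))) {
      site <- dhms[s, ]
      if (!(site$mod_type %in% c("H3K4me1", "H3K4me3", "H3K27ac"))) next
      if (!(abs(site$fold_change) > 1 && site$p_value < 0.05)) next
      if (site$chrom != g$chrom) next
      if (!(site$start < g$tss + window && site$end > g$tss - window)) next
      for (d in seq_len(nrow(deg))) {
        rec <- deg[d, ]
        if (rec$gene_id != g$gene_id) next
        if (rec$cell_line != site$cell_line) next
        if (!(abs(rec$log2fc) > 1 && rec$p_value < 0.05)) next
        if (sign(rec$log2fc) == sign(site$fold_change)) {
          found <- c(found, g$gene_id)
        }
      }
    }
  }
  sort(unique(found))
}

oracle_criterion2 <- function(mms, ceg, genes, regulators, window = 3000L) {
  found <- character(0)
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, , drop = FALSE]
    has_site <- FALSE
    for (s in seq_len(nrow(mms))) {
      site <- mms[s, ]
      if (site$mod_type != "m6A") next
      if (!(abs(site$fold_change) > 1 && site$p_value < 0.05)) next
      if (site$chrom != g$chrom) next
      in_prom <- site$start < g$tss + window && site$end > g$tss - window
      ex <- g$exons[[1]]
      in_exon <- any(site$start < ex$end & ex$start < site$end)
      if (in_prom || in_exon) has_site <- TRUE
    }
    if (!has_site) next
    for (d in seq_len(nrow(ceg))) {
      rec <- ceg[d, ]
      if (rec$gene_id != g$gene_id) next
      if (is.na(rec$p_adj) || rec$p_adj >= 0.05) next
      role <- regulators$role[regulators$regulator_id == rec$regulator_id]
      if (length(role) != 1) next
      if (role %in% c("m6a_writer", "m6a_reader") && rec$rho > 0.3) {
        found <- c(found, g$gene_id)
      }
      if (role == "m6a_eraser" && rec$rho < -0.3) {
        found <- c(found, g$gene_id)
      }
    }
  }
  sort(unique(found))
}
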