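histone_mods <- function() c("H3K4me1", "H3K4me3", "H3K27ac")

# differential-site thresholds shared by the DHMS and MMS filters
filter_sites <- function(sites, fc_threshold = 1, p_threshold = 0.05) {
  sites[abs(sites$fold_change) > fc_threshold &
          sites$p_value < p_threshold, , drop = FALSE]
}

filter_deg <- function(deg, fc_threshold = 1, p_threshold = 0.05) {
  deg[abs(deg$log2fc) > fc_threshold & deg$p_value < p_threshold, , drop = FALSE]
}

# does site [s, e) overlap the promoter window [tss - w, tss + w)?
in_promoter <- function(s, e, tss, window) {
  s < tss + window & e > tss - window
}

# does the site overlap the gene's transcribed region (exon union,
# which contains CDS and 3'UTR) or its promoter window?
in_gene_or_promoter <- function(s, e, gene, window) {
  if (in_promoter(s, e, gene$tss, window)) return(TRUE)
  ex <- gene$exons[[1]]
  any(s < ex$end & ex$start < e)
}

#' EMRG criterion 1 (histone marks)
#'
#' A gene earns criterion-1 evidence when, within a single cell line, at
#' least one differential histone site (|fold-change| > 1, p < 0.05) lies
#' in the gene's +/- 3 kb promoter window AND the gene is differentially
#' expressed (|log2FC| > 1, p < 0.05) in that same cell line with the same
#' direction as the site. Inputs may be pre-filtered; the thresholds are
#' re-applied idempotently.
#'
#' @param dhms Histone site table (with `cell_line`, `mod_type`).
#' @param deg Per-cell-line DEG table (`cell_line`, `gene_id`, `log2fc`,
#'   `p_value`).
#' @param genes A [gene_annotation()].
#' @param window Promoter half-width (default 3000).
#' @return Evidence data.frame(gene_id, mod_type, criterion, cell_line,
#'   site_chrom, site_start, site_end, site_fold_change, deg_log2fc).
#' @export
emrg_criterion1 <- function(dhms, deg, genes, window = 3000L) {
  dhms <- filter_sites(dhms)
  dhms <- dhms[dhms$mod_type %in% histone_mods(), , drop = FALSE]
  deg <- filter_deg(deg)
  out <- list()
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, , drop = FALSE]
    hits <- dhms[dhms$chrom == g$chrom &
                   in_promoter(dhms$start, dhms$end, g$tss, window), ,
                 drop = FALSE]
    if (!nrow(hits)) next
    gdeg <- deg[deg$gene_id == g$gene_id, , drop = FALSE]
    if (!nrow(gdeg)) next
    for (s in seq_len(nrow(hits))) {
      m <- gdeg[gdeg$cell_line == hits$cell_line[s] &
                  sign(gdeg$log2fc) == sign(hits$fold_change[s]), ,
                drop = FALSE]
      if (nrow(m)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g$gene_id, mod_type = hits$mod_type[s], criterion = 1L,
          cell_line = hits$cell_line[s], site_chrom = hits$chrom[s],
          site_start = hits$start[s], site_end = hits$end[s],
          site_fold_change = hits$fold_change[s], deg_log2fc = m$log2fc[1],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty_evidence())
  unique(do.call(rbind, out))
}

#' EMRG criterion 2 (m6A)
#'
#' A gene earns criterion-2 evidence when at least one m6A site
#' (|fold-change| > 1, p < 0.05) lies in the gene (transcribed region or
#' promoter window) in at least one cell line, AND the gene is a CEG:
#' positively correlated (rho > 0.3) with at least one m6A writer/reader,
#' or negatively correlated (rho < -0.3) with at least one m6A eraser
#' (ALKBH5, FTO). By default the correlation must also satisfy adjusted
#' p < 0.05 (set `require_adj = FALSE` to relax).
#'
#' @param mms m6A site table.
#' @param ceg Correlation table from [correlate_with_regulators()].
#' @param genes A [gene_annotation()].
#' @param regulators Regulator table as from [default_regulators()].
#' @param rho_threshold Correlation magnitude threshold (default 0.3).
#' @param require_adj Require adjusted p < 0.05 on the supporting pair.
#' @param window Promoter half-width (default 3000).
#' @return Evidence data.frame as in [emrg_criterion1()], with
#'   `supporting_regulator` and `rho` columns.
#' @export
emrg_criterion2 <- function(mms, ceg, genes, regulators = default_regulators(),
                            rho_threshold = 0.3, require_adj = TRUE,
                            window = 3000L) {
  mms <- filter_sites(mms)
  mms <- mms[mms$mod_type == "m6A", , drop = FALSE]
  role <- regulators$role[match(ceg$regulator_id, regulators$regulator_id)]
  if (anyNA(role)) {
    stop_arg("regulator role missing for: %s",
             paste(unique(ceg$regulator_id[is.na(role)]), collapse = ", "))
  }
  ok_p <- if (require_adj) ceg$p_adj < 0.05 else rep(TRUE, nrow(ceg))
  support <- ceg[ok_p &
                   ((role %in% c("m6a_writer", "m6a_reader") &
                       ceg$rho > rho_threshold) |
                      (role == "m6a_eraser" & ceg$rho < -rho_threshold)), ,
                 drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, , drop = FALSE]
    gsup <- support[support$gene_id == g$gene_id, , drop = FALSE]
    if (!nrow(gsup)) next
    hits <- mms[mms$chrom == g$chrom, , drop = FALSE]
    if (nrow(hits)) {
      inside <- vapply(seq_len(nrow(hits)), function(s) {
        in_gene_or_promoter(hits$start[s], hits$end[s], g, window)
      }, logical(1))
      hits <- hits[inside, , drop = FALSE]
    }
    if (!nrow(hits)) next
    for (s in seq_len(nrow(hits))) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, mod_type = "m6A", criterion = 2L,
        cell_line = hits$cell_line[s], site_chrom = hits$chrom[s],
        site_start = hits$start[s], site_end = hits$end[s],
        site_fold_change = hits$fold_change[s], deg_log2fc = NA_real_,
        supporting_regulator = gsup$regulator_id[1], rho = gsup$rho[1],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    ev <- empty_evidence()
    ev$supporting_regulator <- character(0)
    ev$rho <- numeric(0)
    return(ev)
  }
  unique(do.call(rbind, out))
}

empty_evidence <- function() {
  data.frame(gene_id = character(0), mod_type = character(0),
             criterion = integer(0), cell_line = character(0),
             site_chrom = character(0), site_start = integer(0),
             site_end = integer(0), site_fold_change = numeric(0),
             deg_log2fc = numeric(0), stringsAsFactors = FALSE)
}

#' Build the EMRG catalogue
#'
#' Unions the evidence lists per gene, tallies the supporting modification
#' types, counts genes supported by 1-4 modification types (the
#' multi-modification overlap partition), and extracts the EMRL subset
#' (entries with the lncRNA biotype).
#'
#' @param evidence_list List of evidence data.frames from the criterion
#'   functions (order and duplication irrelevant).
#' @param genes A [gene_annotation()].
#' @return List with `catalog` (gene_id, biotype, mod_types, n_mod_types,
#'   n_evidence), `per_mod_counts`, `overlap_counts` (named by number of
#'   supporting types), `emrls` and `evidence`.
#' @export
build_catalog <- function(evidence_list, genes) {
  common <- c("gene_id", "mod_type", "criterion", "cell_line", "site_chrom",
              "site_start", "site_end", "site_fold_change", "deg_log2fc")
  ev <- do.call(rbind, lapply(evidence_list, function(e) {
    if (!"supporting_regulator" %in% names(e)) {
      e$supporting_regulator <- rep(NA_character_, nrow(e))
    }
    if (!"rho" %in% names(e)) e$rho <- rep(NA_real_, nrow(e))
    e[, c(common, "supporting_regulator", "rho"), drop = FALSE]
  }))
  ev <- unique(ev)
  ev <- ev[order(ev$gene_id, ev$mod_type, ev$site_start), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev)) {
    split_ev <- split(ev, ev$gene_id)
    catalog <- data.frame(
      gene_id = names(split_ev),
      biotype = genes$biotype[match(names(split_ev), genes$gene_id)],
      mod_types = vapply(split_ev, function(e)
        paste(sort(unique(e$mod_type)), collapse = ","), character(1)),
      n_mod_types = vapply(split_ev, function(e)
        length(unique(e$mod_type)), integer(1)),
      n_evidence = vapply(split_ev, nrow, integer(1)),
      stringsAsFactors = FALSE
    )
    rownames(catalog) <- NULL
  } else {
    catalog <- data.frame(gene_id = character(0), biotype = character(0),
                          mod_types = character(0), n_mod_types = integer(0),
                          n_evidence = integer(0), stringsAsFactors = FALSE)
  }
  per_mod <- vapply(mod_types(), function(m)
    length(unique(ev$gene_id[ev$mod_type == m])), integer(1))
  overlap <- vapply(1:4, function(k) sum(catalog$n_mod_types == k), integer(1))
  names(overlap) <- as.character(1:4)
  list(catalog = catalog,
       per_mod_counts = per_mod,
       overlap_counts = overlap,
       emrls = catalog$gene_id[!is.na(catalog$biotype) &
                                 catalog$biotype == "lncRNA"],
       evidence = ev)
}
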