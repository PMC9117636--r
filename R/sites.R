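mod_types <- function() c("H3K4me1", "H3K4me3", "H3K27ac", "m6A")

region_levels <- function() {
  c("promoter_lt1kb", "promoter_1to2kb", "promoter_2to3kb",
    "utr3", "cds", "exon", "intron", "distal")
}

#' Read a modification-site table
#'
#' BED-like TSV with header and columns `chrom,start,end,strand,
#' fold_change,p_value` (plus optional `cell_line`). Coordinates are
#' 0-based half-open. Rows violating the site invariants
#' (`start < end`, `p_value` in (0,1]) raise an error naming the row;
#' output is sorted by (chrom, start).
#'
#' @param path Path to the TSV.
#' @param mod_type One of `H3K4me1`, `H3K4me3`, `H3K27ac`, `m6A`.
#' @return data.frame of sites with a `mod_type` column.
#' @export
read_site_table <- function(path, mod_type) {
  mod_type <- match.arg(mod_type, mod_types())
  df <- read_tsv(path)
  req <- c("chrom", "start", "end", "strand", "fold_change", "p_value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_arg("site table %s missing column(s): %s",
                             path, paste(miss, collapse = ", "))
  if (!"cell_line" %in% names(df)) df$cell_line <- NA_character_
  validate_sites(df)
  df$mod_type <- mod_type
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "strand", "mod_type",
         "fold_change", "p_value", "cell_line")]
}

validate_sites <- function(df) {
  bad <- which(!(df$start < df$end) | df$start < 0)
  if (length(bad)) stop_arg("invalid interval at row %d (need 0 <= start < end)",
                            bad[1])
  bad <- which(!(df$p_value > 0 & df$p_value <= 1))
  if (length(bad)) stop_arg("p_value out of (0,1] at row %d", bad[1])
  invisible(TRUE)
}

#' Write a site table
#' @param sites data.frame as from [read_site_table()].
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("chrom", "start", "end", "strand", "fold_change",
            "p_value", "cell_line")
  write_tsv(sites[, cols], path)
}

#' Classify a site's position relative to one gene
#'
#' The promoter is the window `[tss - window, tss + window)` and is split
#' into <1 kb, 1-2 kb and 2-3 kb distance bins; a site overlapping the
#' window is assigned the bin of its base closest to the TSS. Outside the
#' promoter, precedence is 3'UTR > CDS > exon > intron > distal. A site on
#' a different chromosome is `distal`.
#'
#' @param site_start,site_end 0-based half-open site interval.
#' @param site_chrom Site chromosome.
#' @param gene One row of a [gene_annotation()] (a data.frame slice).
#' @param window Promoter half-width in bp (default 3000).
#' @return One of `promoter_lt1kb`, `promoter_1to2kb`, `promoter_2to3kb`,
#'   `utr3`, `cds`, `exon`, `intron`, `distal`.
#' @export
classify_site_region <- function(site_chrom, site_start, site_end, gene,
                                 window = 3000L) {
  if (window <= 0) stop_arg("window must be > 0")
  if (site_start >= site_end) stop_arg("need site_start < site_end")
  if (site_chrom != gene$chrom) return("distal")
  tss <- gene$tss
  # overlap with [tss - window, tss + window)
  lo <- max(site_start, tss - window)
  hi <- min(site_end, tss + window)
  if (lo < hi) {
    # minimum |base - tss| over overlapping bases
    d <- if (tss >= lo && tss < hi) 0L else min(abs(lo - tss), abs(hi - 1L - tss))
    return(if (d < 1000) "promoter_lt1kb"
           else if (d < 2000) "promoter_1to2kb"
           else "promoter_2to3kb")
  }
  overlaps_any <- function(parts) {
    nrow(parts) > 0 && any(site_start < parts$end & parts$start < site_end)
  }
  if (overlaps_any(gene$utr3[[1]])) return("utr3")
  if (overlaps_any(gene$cds[[1]])) return("cds")
  if (overlaps_any(gene$exons[[1]])) return("exon")
  if (site_start < gene$end && gene$start < site_end) return("intron")
  "distal"
}

#' Classify every site against its nearest gene
#'
#' Each site is labelled against the gene whose TSS is nearest (same
#' chromosome); used to tabulate the site-region distribution of each
#' modification type (promoter bins for histone marks, 3'UTR/exon for m6A).
#'
#' @param sites Site data.frame.
#' @param genes A [gene_annotation()].
#' @param window Promoter half-width in bp.
#' @return `sites` with `region` and `nearest_gene` columns.
#' @export
classify_sites <- function(sites, genes, window = 3000L) {
  region <- character(nrow(sites))
  nearest <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cand <- which(genes$chrom == sites$chrom[i])
    if (!length(cand)) {
      region[i] <- "distal"; nearest[i] <- NA_character_
      next
    }
    mid <- (sites$start[i] + sites$end[i] - 1) / 2
    j <- cand[which.min(abs(genes$tss[cand] - mid))]
    region[i] <- classify_site_region(sites$chrom[i], sites$start[i],
                                      sites$end[i], genes[j, , drop = FALSE],
                                      window)
    nearest[i] <- genes$gene_id[j]
  }
  sites$region <- factor(region, levels = region_levels())
  sites$nearest_gene <- nearest
  sites
}
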