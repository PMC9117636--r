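## Gene annotation container
##
## A `gene_annotation` is a data.frame with one row per gene and columns
##   gene_id, biotype ∈ {protein_coding, lncRNA, other},
##   chrom, start, end  (0-based, half-open), strand ∈ {+, -, .},
##   tss (0-based position of the transcription start base: `start` on the
##   plus strand, `end - 1` on the minus strand),
## plus list-columns exons, cds, utr3, each holding a data.frame with
## integer columns start, end (0-based half-open, same chrom/strand as the
## gene; cds and utr3 may have zero rows, e.g. for lncRNAs).

#' Construct and validate a gene annotation
#'
#' @param genes data.frame with the columns documented above.
#' @return The validated object, classed `gene_annotation`.
#' @export
gene_annotation <- function(genes) {
  req <- c("gene_id", "biotype", "chrom", "start", "end", "strand",
           "tss", "exons", "cds", "utr3")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop_arg("gene annotation missing column(s): %s",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop_arg("duplicated gene_id")
  if (any(genes$start < 0 | genes$start >= genes$end)) {
    stop_arg("gene bodies must satisfy 0 <= start < end")
  }
  if (any(genes$tss < genes$start | genes$tss >= genes$end)) {
    stop_arg("tss must lie within the gene body")
  }
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) stop_arg("gene %s has no exons", genes$gene_id[i])
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start >= ex$end)) stop_arg("gene %s: empty exon", genes$gene_id[i])
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop_arg("gene %s: overlapping exons", genes$gene_id[i])
    }
    for (part in c("cds", "utr3")) {
      pp <- genes[[part]][[i]]
      if (nrow(pp) && !all(contained_in(pp, ex))) {
        stop_arg("gene %s: %s not contained in exons", genes$gene_id[i], part)
      }
    }
  }
  class(genes) <- unique(c("gene_annotation", class(genes)))
  genes
}

# are all intervals of `a` contained in the union of intervals of `b`?
contained_in <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    cov <- b[b$start <= a$start[i] & b$end >= a$end[i], , drop = FALSE]
    nrow(cov) > 0
  }, logical(1))
}

collapse_biotype <- function(x) {
  lnc <- c("lncRNA", "lincRNA", "antisense", "processed_transcript",
           "sense_intronic", "sense_overlapping", "3prime_overlapping_ncRNA",
           "bidirectional_promoter_lncRNA", "macro_lncRNA", "non_coding")
  ifelse(x == "protein_coding", "protein_coding",
         ifelse(x %in% lnc, "lncRNA", "other"))
}

#' Read a GENCODE-dialect GTF into a gene annotation
#'
#' Parses `gene`, `exon`, `CDS` and `three_prime_UTR`/`UTR` features; the
#' 1-based closed GTF coordinates are converted to the package's 0-based
#' half-open convention. Biotype is taken from the `gene_type` attribute
#' (lncRNA-class biotypes collapsed to `lncRNA`). Genes without exon
#' features are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @return A [gene_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id") %in% names(meta))) {
    stop_arg("GTF lacks type/gene_id attributes: %s", path)
  }
  type <- as.character(meta$type)
  gid <- as.character(meta$gene_id)
  # 1-based closed -> 0-based half-open
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, gene_id = gid,
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  gtype <- if ("gene_type" %in% names(meta)) as.character(meta$gene_type)
           else rep("other", nrow(df))
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  gene_bt <- collapse_biotype(gtype[df$type == "gene"])
  keep <- logical(nrow(gene_rows))
  exons <- cds <- utr3 <- vector("list", nrow(gene_rows))
  part_of <- function(feat_types, g) {
    sub <- df[df$type %in% feat_types & df$gene_id == g,
              c("start", "end"), drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  for (i in seq_len(nrow(gene_rows))) {
    g <- gene_rows$gene_id[i]
    ex <- part_of("exon", g)
    if (nrow(ex) == 0) {
      warning(sprintf("gene %s has no exons; skipped", g), call. = FALSE)
      next
    }
    keep[i] <- TRUE
    exons[[i]] <- ex
    cds[[i]] <- part_of("CDS", g)
    utr3[[i]] <- part_of(c("three_prime_UTR", "three_prime_utr"), g)
  }
  out <- data.frame(
    gene_id = gene_rows$gene_id,
    biotype = gene_bt,
    chrom = gene_rows$chrom,
    start = gene_rows$start,
    end = gene_rows$end,
    strand = gene_rows$strand,
    stringsAsFactors = FALSE
  )
  out$tss <- ifelse(out$strand == "-", out$end - 1L, out$start)
  out$exons <- exons
  out$cds <- cds
  out$utr3 <- utr3
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  gene_annotation(out)
}

# cheap structural validation so malformed lines fail with a line number
# (rtracklayer's own errors do not name the offending line)
check_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop_arg("malformed GTF line %d in %s", i, path)
    }
  }
  invisible(TRUE)
}

#' Write a gene annotation as a GENCODE-dialect GTF
#'
#' Emits `gene`, `exon`, `CDS` and `three_prime_UTR` features with
#' `gene_id` and `gene_type` attributes; coordinates are converted back to
#' the GTF's 1-based closed convention. `read_gtf(write_gtf(x))` is an
#' identity on all fields.
#'
#' @param genes A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bt_out <- c(protein_coding = "protein_coding", lncRNA = "lncRNA",
              other = "misc_RNA")
  fmt <- function(chrom, start0, end0, strand, type, gid, gtype) {
    sprintf("%s\temdgc\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_type \"%s\";",
            chrom, type, start0 + 1L, end0, strand, gid, gtype)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gt <- bt_out[[g$biotype]]
    writeLines(fmt(g$chrom, g$start, g$end, g$strand, "gene", g$gene_id, gt), con)
    parts <- list(exon = genes$exons[[i]], CDS = genes$cds[[i]],
                  three_prime_UTR = genes$utr3[[i]])
    for (type in names(parts)) {
      pp <- parts[[type]]
      for (j in seq_len(nrow(pp))) {
        writeLines(fmt(g$chrom, pp$start[j], pp$end[j], g$strand, type,
                       g$gene_id, gt), con)
      }
    }
  }
  invisible(path)
}
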