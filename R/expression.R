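#' Expression dataset
#'
#' Bundles a genes x samples matrix of log2-scale normalized expression
#' with per-sample metadata. `samples` must contain `sample_id` and
#' `cohort`; optional columns are `os_time` (days), `os_event` (0/1),
#' `ici_response` (`responder`/`non_responder`) and `cluster` (truth or
#' assigned subtype labels). Mutations are carried separately as a binary
#' samples x genes matrix (see [simulate_mutations()]).
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data.frame of per-sample metadata.
#' @param mutations Optional binary samples x genes matrix.
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, samples, mutations = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_arg("values must have gene rownames and sample colnames")
  }
  if (anyNA(values)) stop_arg("expression matrix must not contain NA")
  if (!all(c("sample_id", "cohort") %in% names(samples))) {
    stop_arg("samples needs columns sample_id, cohort")
  }
  if (!identical(colnames(values), samples$sample_id)) {
    stop_arg("sample order mismatch between values and samples")
  }
  if ("os_time" %in% names(samples)) {
    tt <- samples$os_time
    if (any(!is.na(tt) & tt <= 0)) stop_arg("os_time must be > 0 when present")
  }
  if (!is.null(mutations) &&
      !identical(rownames(mutations), samples$sample_id)) {
    stop_arg("mutation matrix rows must match sample ids")
  }
  structure(list(values = values, samples = samples, mutations = mutations),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d genes x %d samples (%d cohort%s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$cohort)),
              if (length(unique(x$samples$cohort)) == 1) "" else "s"))
  invisible(x)
}

#' Read an expression matrix TSV
#'
#' First column `gene_id`, remaining header fields are sample ids.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id") stop_arg("first column must be gene_id: %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_arg("expression matrix contains NA: %s", path)
  m
}

#' Write an expression matrix TSV
#' @param values Matrix as in [expr_dataset()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a clinical table keyed by sample_id
#' @param path TSV with columns sample_id, cohort and optional os_time,
#'   os_event, ici_response, cluster.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stop_arg("clinical table needs sample_id")
  df
}

#' Read a binary mutation matrix (samples x genes)
#' @param path TSV: first column sample_id, remaining columns 0/1 per gene.
#' @return Binary integer matrix with sample rownames.
#' @export
read_mutation_tsv <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample_id") stop_arg("first column must be sample_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop_arg("mutation matrix must be 0/1")
  m
}

#' Write a binary mutation matrix
#' @param mutations Binary samples x genes matrix.
#' @param path Output path.
#' @export
write_mutation_tsv <- function(mutations, path) {
  df <- data.frame(sample_id = rownames(mutations), mutations,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
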