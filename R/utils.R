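#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor kmeans hclust cutree p.adjust pchisq pt pnorm
#'   quantile fisher.test rexp runif rnorm rbinom prcomp sd median setNames
#'   complete.cases
#' @importFrom utils read.delim write.table
NULL

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic TSV writer: fixed column order, no quoting, "." decimal,
# full precision so that identical inputs give byte-identical files
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
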