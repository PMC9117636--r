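#' The 43 epigenetic regulators
#'
#' Returns the packaged catalogue of 43 epigenetic regulators spanning the
#' four modification types analysed by the pipeline: histone
#' methyltransferases and demethylases (H3K4me1/H3K4me3), histone acetylases
#' and deacetylases (H3K27ac), and the m6A writers, readers and erasers.
#' The 22 m6A regulators (10 writers, 10 readers, 2 erasers ALKBH5 and FTO)
#' drive the correlatively-expressed-gene (CEG) screen.
#'
#' @param path Optional path to a two-column TSV (`regulator_id`, `role`)
#'   overriding the packaged default.
#' @return A data.frame with columns `regulator_id` and `role`; role is one
#'   of `histone_writer`, `histone_eraser`, `histone_acetylase`,
#'   `histone_deacetylase`, `m6a_writer`, `m6a_reader`, `m6a_eraser`.
#' @export
#' @examples
#' regs <- default_regulators()
#' table(regs$role)
default_regulators <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "epigenetic_regulators.tsv",
                        package = "emdgc", mustWork = TRUE)
  }
  regs <- read_tsv(path)
  if (!all(c("regulator_id", "role") %in% names(regs))) {
    stop_arg("regulator table needs columns regulator_id, role")
  }
  bad <- setdiff(regs$role, regulator_roles())
  if (length(bad)) stop_arg("unknown regulator role(s): %s",
                            paste(bad, collapse = ", "))
  regs
}

regulator_roles <- function() {
  c("histone_writer", "histone_eraser", "histone_acetylase",
    "histone_deacetylase", "m6a_writer", "m6a_reader", "m6a_eraser")
}

#' Subset a regulator table to the m6A regulators
#'
#' @param regs Regulator data.frame as from [default_regulators()].
#' @param roles m6A roles to keep.
#' @return Subset data.frame.
#' @export
m6a_regulators <- function(regs,
                           roles = c("m6a_writer", "m6a_reader", "m6a_eraser")) {
  regs[regs$role %in% roles, , drop = FALSE]
}
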