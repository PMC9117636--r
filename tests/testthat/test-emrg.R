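site_row <- function(chrom, start, end, mod_type, fc, p = 0.01,
                     cell_line = "SNU719") {
  data.frame(chrom = chrom, start = start, end = end, strand = "+",
             mod_type = mod_type, fold_change = fc, p_value = p,
             cell_line = cell_line, stringsAsFactors = FALSE)
}

deg_row <- function(gene_id, log2fc, p = 0.001, cell_line = "SNU719") {
  data.frame(cell_line = cell_line, gene_id = gene_id, log2fc = log2fc,
             p_value = p, stringsAsFactors = FALSE)
}

ceg_row <- function(gene_id, regulator_id, rho, p_adj = 0.001) {
  data.frame(gene_id = gene_id, regulator_id = regulator_id, rho = rho,
             p_value = p_adj, p_adj = p_adj, stringsAsFactors = FALSE)
}

test_that("criterion 1 needs promoter site and same-direction DEG in one cell line", {
  genes <- toy_genes(2, strand = c("+", "+"))  # T01 tss=10000, T02 tss=60000
  site <- site_row("chrT", 9600, 9900, "H3K4me1", 2)

  ev <- emrg_criterion1(site, deg_row("T01", 1.5), genes)
  expect_equal(unique(ev$gene_id), "T01")
  expect_equal(ev$criterion, 1L)

  # direction mismatch: no evidence
  expect_equal(nrow(emrg_criterion1(site, deg_row("T01", -1.5), genes)), 0)
  # DEG in a different cell line: no evidence
  expect_equal(nrow(emrg_criterion1(site, deg_row("T01", 1.5, cell_line = "NCC24"),
                                    genes)), 0)
  # sub-threshold site or DEG: no evidence
  expect_equal(nrow(emrg_criterion1(site_row("chrT", 9600, 9900, "H3K4me1", 0.5),
                                    deg_row("T01", 1.5), genes)), 0)
  expect_equal(nrow(emrg_criterion1(site, deg_row("T01", 0.5), genes)), 0)
  # empty inputs are fine
  expect_equal(nrow(emrg_criterion1(site[0, ], deg_row("T01", 1.5), genes)), 0)
})

test_that("criterion 2 pools writers/readers positively, erasers negatively", {
  genes <- toy_genes(2)
  # m6A site in T01's 3'UTR (utr3 = [15700, 16000))
  mms <- site_row("chrT", 15750, 15850, "m6A", 2, cell_line = "AGS")

  ev <- emrg_criterion2(mms, ceg_row("T01", "METTL3", 0.5), genes)
  expect_equal(unique(ev$gene_id), "T01")
  expect_equal(ev$supporting_regulator[1], "METTL3")

  # positive correlation with an eraser does not qualify
  expect_equal(nrow(emrg_criterion2(mms, ceg_row("T01", "FTO", 0.5), genes)), 0)
  # negative correlation with an eraser does
  expect_equal(nrow(emrg_criterion2(mms, ceg_row("T01", "FTO", -0.5), genes)), 1)
  # adjusted p gate is enforced by default and relaxable
  weak <- ceg_row("T01", "METTL3", 0.5, p_adj = 0.2)
  expect_equal(nrow(emrg_criterion2(mms, weak, genes)), 0)
  expect_equal(nrow(emrg_criterion2(mms, weak, genes, require_adj = FALSE)), 1)
  # unknown regulator role errors
  expect_error(emrg_criterion2(mms, ceg_row("T01", "NOTAREG", 0.5), genes),
               "NOTAREG")
})

test_that("criteria match a literal triple-loop oracle on random fixtures", {
  genes <- toy_genes(5)
  regs <- default_regulators()
  m6a <- m6a_regulators(regs)$regulator_id
  lines <- c("SNU719", "NCC24", "YCC10")
  set.seed(31)
  for (r in 1:100) {
    ns <- sample(3:10, 1)
    anchor <- genes$tss[sample(5, ns, replace = TRUE)]
    sites <- data.frame(
      chrom = sample(c("chrT", "chrZ"), ns, replace = TRUE, prob = c(.9, .1)),
      start = anchor + sample(-5000:5000, ns, replace = TRUE),
      end = 0L, strand = "+",
      mod_type = sample(mod_types(), ns, replace = TRUE),
      fold_change = runif(ns, -3, 3),
      p_value = runif(ns, 0.001, 0.2),
      cell_line = sample(lines, ns, replace = TRUE),
      stringsAsFactors = FALSE)
    sites$end <- sites$start + sample(50:900, ns, replace = TRUE)
    nd <- sample(3:10, 1)
    deg <- data.frame(
      cell_line = sample(lines, nd, replace = TRUE),
      gene_id = sample(genes$gene_id, nd, replace = TRUE),
      log2fc = runif(nd, -3, 3), p_value = runif(nd, 0.001, 0.2),
      stringsAsFactors = FALSE)
    nc <- sample(3:10, 1)
    ceg <- data.frame(
      gene_id = sample(genes$gene_id, nc, replace = TRUE),
      regulator_id = sample(m6a, nc, replace = TRUE),
      rho = runif(nc, -0.9, 0.9), p_value = 0.001,
      p_adj = sample(c(0.001, 0.2), nc, replace = TRUE),
      stringsAsFactors = FALSE)

    ev1 <- emrg_criterion1(sites, deg, genes)
    expect_identical(sort(unique(ev1$gene_id)),
                     oracle_criterion1(sites, deg, genes))
    ev2 <- emrg_criterion2(sites, ceg, genes)
    expect_identical(sort(unique(ev2$gene_id)),
                     oracle_criterion2(sites, ceg, genes, regs))
  }
})

test_that("catalogue unions evidence, partitions overlaps, extracts EMRLs", {
  genes <- toy_genes(4, biotype = c("protein_coding", "protein_coding",
                                    "lncRNA", "lncRNA"))
  ev1 <- rbind(
    data.frame(gene_id = "T01", mod_type = "H3K4me1", criterion = 1L,
               cell_line = "SNU719", site_chrom = "chrT", site_start = 9500L,
               site_end = 9700L, site_fold_change = 2, deg_log2fc = 1.5,
               stringsAsFactors = FALSE),
    data.frame(gene_id = "T03", mod_type = "H3K27ac", criterion = 1L,
               cell_line = "NCC24", site_chrom = "chrT", site_start = 109000L,
               site_end = 109200L, site_fold_change = -2, deg_log2fc = -1.2,
               stringsAsFactors = FALSE))
  ev2 <- data.frame(gene_id = c("T01", "T03"), mod_type = "m6A",
                    criterion = 2L, cell_line = "AGS", site_chrom = "chrT",
                    site_start = c(15750L, 115700L),
                    site_end = c(15850L, 115800L), site_fold_change = 2,
                    deg_log2fc = NA_real_, supporting_regulator = "METTL3",
                    rho = 0.5, stringsAsFactors = FALSE)
  cat1 <- build_catalog(list(ev1, ev2), genes)
  expect_equal(nrow(cat1$catalog), 2)
  expect_equal(cat1$catalog$n_mod_types, c(2L, 2L))
  expect_equal(unname(cat1$overlap_counts), c(0L, 2L, 0L, 0L))
  expect_equal(sum(cat1$overlap_counts), nrow(cat1$catalog))
  expect_equal(cat1$emrls, "T03")
  expect_equal(unname(cat1$per_mod_counts[c("H3K4me1", "m6A")]), c(1L, 2L))

  # invariant to evidence order and duplication
  cat2 <- build_catalog(list(ev2, ev1, ev1), genes)
  expect_identical(cat1$catalog, cat2$catalog)

  # monotone: adding evidence never removes a gene
  extra <- ev1[1, ]; extra$gene_id <- "T02"
  cat3 <- build_catalog(list(ev1, ev2, extra), genes)
  expect_true(all(cat1$catalog$gene_id %in% cat3$catalog$gene_id))

  # empty catalogue
  cat0 <- build_catalog(list(ev1[0, ]), genes)
  expect_equal(nrow(cat0$catalog), 0)
  expect_equal(sum(cat0$overlap_counts), 0L)
})
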