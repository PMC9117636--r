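small_cfg <- function(seed = 2, ...) {
  simulate_config(seed = seed, n_genes = 120, frac_lncrna = 0.3,
                  n_samples = 60, marker_block = 4, set1_size = 8,
                  set2_size = 6, n_background_sites = 60, ...)
}

test_that("annotation generator: counts, determinism, disjoint promoters", {
  cfg <- small_cfg()
  genes <- simulate_annotation(cfg)
  expect_equal(nrow(genes), 120)
  expect_equal(sum(genes$biotype == "lncRNA"), round(0.3 * 120))
  expect_true(all(default_regulators()$regulator_id %in% genes$gene_id))

  tmp1 <- withr::local_tempfile(); tmp2 <- withr::local_tempfile()
  write_gtf(genes, tmp1)
  write_gtf(simulate_annotation(cfg), tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))

  # brute-force pairwise check that +/-3kb promoter windows never collide
  lo <- genes$tss - 3000L; hi <- genes$tss + 3000L
  for (i in seq_len(nrow(genes) - 1)) {
    expect_true(all(hi[i] <= lo[-seq_len(i)] | lo[i] >= hi[-seq_len(i)]))
  }
})

test_that("site generator plants qualifying sites and sub-threshold background", {
  cfg <- small_cfg()
  genes <- simulate_annotation(cfg)
  planted <- default_planting(cfg)
  sites <- simulate_sites(cfg, genes, planted)
  expect_true(all(sites$start < sites$end))
  expect_true(all(sites$p_value > 0 & sites$p_value <= 1))

  # each planted histone site overlaps its gene's promoter with |fc| > 1
  hist <- planted[planted$in_promoter, ]
  for (i in seq_len(nrow(hist))) {
    g <- genes[genes$gene_id == hist$gene_id[i], , drop = FALSE]
    cand <- sites[sites$mod_type == hist$mod_type[i] &
                    sites$start < g$tss + 3000 & sites$end > g$tss - 3000, ]
    expect_gte(nrow(cand), 1)
    expect_true(all(abs(cand$fold_change) > 1 & cand$p_value < 0.05))
  }
  # m6A on lncRNA (no 3'UTR) falls back into an exon
  lnc <- planted$gene_id[!planted$in_promoter][1]
  g <- genes[genes$gene_id == lnc, , drop = FALSE]
  ex <- g$exons[[1]]
  m6a_near <- sites[sites$mod_type == "m6A" & sites$start >= g$start &
                      sites$end <= g$end, ]
  expect_gte(nrow(m6a_near), 1)
  expect_true(any(m6a_near$start < ex$end[nrow(ex)] &
                    m6a_near$end > ex$start[nrow(ex)]))

  # background sites never pass the differential-site thresholds
  keep <- emdgc:::filter_sites(sites)
  expect_equal(nrow(keep), nrow(planted))
  # planting a gene missing from the annotation errors
  bad <- planted; bad$gene_id[1] <- "NOT_A_GENE"
  expect_error(simulate_sites(cfg, genes, bad), "NOT_A_GENE")
})

test_that("expression generator plants cluster shifts and correlations", {
  cfg <- simulate_config(seed = 11, n_samples = 200, effect_size = 2,
                         noise_sd = 0.5)
  genes <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, genes)
  expect_false(anyNA(expr$values))
  truth <- emdgc:::study_layout(cfg)
  emd <- expr$samples$cluster == "C4"

  # planted set1 shift recovered within 3 standard errors
  d <- rowMeans(expr$values[truth$set1, emd]) -
    rowMeans(expr$values[truth$set1, !emd])
  se_mean <- 0.5 * sqrt(1 / sum(emd) + 1 / sum(!emd)) / sqrt(length(d))
  expect_lt(abs(mean(d) - 2), 3 * se_mean)

  # planted shift-free pair: Spearman r close to corr_strength
  pr <- truth$corr_pairs[1, ]
  r <- cor(expr$values[pr$target, ], expr$values[pr$regulator, ],
           method = "spearman")
  expect_gt(r, 0.6); expect_lt(r, 0.95)

  # FTO up / HDAC1 down in the EMD cluster
  expect_gt(mean(expr$values["FTO", emd]) - mean(expr$values["FTO", !emd]), 1)
  expect_lt(mean(expr$values["HDAC1", emd]) - mean(expr$values["HDAC1", !emd]), -1)
})

test_that("null configuration yields an exchangeable matrix", {
  cfg <- small_cfg(seed = 4, effect_size = 0, corr_strength = 0)
  genes <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, genes)
  truth <- emdgc:::study_layout(cfg)
  emd <- expr$samples$cluster == paste0("C", cfg$n_clusters)
  d <- rowMeans(expr$values[truth$set1, emd]) -
    rowMeans(expr$values[truth$set1, !emd])
  expect_lt(max(abs(d)), 4 * cfg$noise_sd * sqrt(1 / sum(emd) + 1 / sum(!emd)))
})

test_that("clinical generator: exclusion floor, null independence, hazard recovery", {
  cfg <- simulate_config(seed = 8, n_samples = 500, hazard_coef = 0)
  score <- with(list(), {set.seed(1); rnorm(500)})
  clin <- simulate_clinical(cfg, score)
  expect_true(all(clin$os_time > 30))
  expect_lt(abs(cor(score, clin$os_time, method = "spearman")), 0.1)

  cfg1 <- simulate_config(seed = 8, n_samples = 500, hazard_coef = 1)
  clin1 <- simulate_clinical(cfg1, score)
  z <- (score - mean(score)) / sd(score)
  fit <- survival::coxph(survival::Surv(clin1$os_time, clin1$os_event) ~ z,
                         ties = "breslow")
  expect_lt(abs(unname(coef(fit)) - 1), 0.25)
})

test_that("mutation generator hits the configured odds ratios", {
  pairs <- data.frame(gene_a = "KMT2D", gene_b = "METTL3", odds_ratio = 20)
  hits <- vapply(1:10, function(s) {
    cfg <- simulate_config(seed = 100 + s, n_samples = 300,
                           comut_pairs = pairs)
    m <- simulate_mutations(cfg, sprintf("P%03d", 1:300))
    res <- comutation_test(m, c("KMT2D", "METTL3"))
    res$p_value < 0.05 && res$direction == "co_occurrence"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # with no planted pairs the sample odds ratios sit near 1
  ors <- vapply(1:10, function(s) {
    cfg <- simulate_config(seed = 200 + s, n_samples = 300,
                           comut_pairs = data.frame(gene_a = character(0),
                                                    gene_b = character(0),
                                                    odds_ratio = numeric(0)))
    m <- simulate_mutations(cfg, sprintf("P%03d", 1:300))
    res <- comutation_test(m, c("KMT2A", "WTAP", "YTHDF2", "HDAC2"))
    median(res$odds_ratio, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(median(ors) - 1), 0.5)
})

test_that("generated artifacts survive the readers' round trip", {
  cfg <- small_cfg(seed = 9)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(study, dir)
  genes <- read_gtf(file.path(dir, "annotation.gtf"))
  expect_equal(genes$gene_id, study$annotation$gene_id)
  dhms <- read_site_table(file.path(dir, "dhms.tsv"), "H3K4me1")
  expect_equal(nrow(dhms), nrow(study$dhms))
  vals <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(dim(vals), dim(study$expr$values))
  expect_equal(vals[3, 7], study$expr$values[3, 7], tolerance = 1e-9)
  muts <- read_mutation_tsv(file.path(dir, "mutations.tsv"))
  expect_identical(unname(muts), unname(study$expr$mutations))
  clin <- read_clinical_tsv(file.path(dir, "clinical.tsv"))
  expect_equal(clin$sample_id, study$expr$samples$sample_id)
})
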