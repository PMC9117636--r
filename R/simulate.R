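#' Configuration for the synthetic gastric-cancer study
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' one coherent synthetic study: a single-chromosome annotation mixing the
#' 43 epigenetic regulators with filler protein-coding genes and lncRNAs,
#' four planted patient clusters (the last one EMD-like: elevated set1-like
#' genes and high FTO, suppressed set2-like genes and low HDAC1), per-cluster
#' lncRNA marker blocks carrying m6A sites and regulator correlations (so
#' they become EMRLs), exponential survival whose hazard rises with the
#' planted score, and ICI response anti-correlated with it.
#'
#' @param seed Integer RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Total genes (>= 43 regulators + planted sets).
#' @param frac_lncrna Fraction of genes given the lncRNA biotype.
#' @param n_samples Number of patients.
#' @param n_clusters Planted sample clusters (last = EMD-like).
#' @param set1_size,set2_size Planted EMD-up / EMD-down protein-coding
#'   signature sizes.
#' @param marker_block lncRNA markers per cluster (these become the EMRLs).
#' @param effect_size Mean log2 shift of planted genes in their cluster.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param hazard_coef Log-hazard increase per SD of the planted score.
#' @param corr_strength Planted gene-regulator correlation in (0,1).
#' @param comut_pairs data.frame(gene_a, gene_b, odds_ratio) of planted
#'   co-mutations among regulators.
#' @param mut_rate Background per-gene mutation probability.
#' @param n_background_sites Distal sub-threshold sites added per site table.
#' @param baseline_median_os Baseline median overall survival in days.
#' @param censor_max Upper bound of the uniform censoring time (days).
#' @param response_slope Logistic slope of responder probability against the
#'   standardized score (negative association).
#' @return A validated `sim_config` list.
#' @export
simulate_config <- function(seed = 1L,
                            n_genes = 400L,
                            frac_lncrna = 0.25,
                            n_samples = 120L,
                            n_clusters = 4L,
                            set1_size = 40L,
                            set2_size = 25L,
                            marker_block = 12L,
                            effect_size = 2,
                            noise_sd = 1,
                            hazard_coef = 1,
                            corr_strength = 0.8,
                            comut_pairs = NULL,
                            mut_rate = 0.12,
                            n_background_sites = 150L,
                            baseline_median_os = 730,
                            censor_max = 3650,
                            response_slope = 2) {
  if (is.null(comut_pairs)) {
    comut_pairs <- data.frame(gene_a = c("KMT2D", "KMT2C"),
                              gene_b = c("METTL3", "IGF2BP2"),
                              odds_ratio = c(10, 8),
                              stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_lncrna = frac_lncrna, n_samples = as.integer(n_samples),
              n_clusters = as.integer(n_clusters),
              set1_size = as.integer(set1_size),
              set2_size = as.integer(set2_size),
              marker_block = as.integer(marker_block),
              effect_size = effect_size, noise_sd = noise_sd,
              hazard_coef = hazard_coef, corr_strength = corr_strength,
              comut_pairs = comut_pairs, mut_rate = mut_rate,
              n_background_sites = as.integer(n_background_sites),
              baseline_median_os = baseline_median_os,
              censor_max = censor_max, response_slope = response_slope)
  if (cfg$n_clusters < 2) stop_arg("n_clusters must be >= 2")
  if (cfg$noise_sd <= 0) stop_arg("noise_sd must be > 0")
  if (!is.finite(cfg$hazard_coef)) stop_arg("hazard_coef must be finite")
  if (cfg$frac_lncrna <= 0 || cfg$frac_lncrna >= 1) {
    stop_arg("frac_lncrna must be in (0,1)")
  }
  if (cfg$set1_size + cfg$set2_size > cfg$n_genes) {
    stop_arg("set1_size + set2_size exceeds n_genes")
  }
  n_lnc <- round(cfg$frac_lncrna * cfg$n_genes)
  if (n_lnc < cfg$n_clusters * cfg$marker_block) {
    stop_arg("not enough lncRNAs for %d marker blocks of %d",
             cfg$n_clusters, cfg$marker_block)
  }
  n_fill_pcg <- cfg$n_genes - 43L - n_lnc
  if (n_fill_pcg < cfg$set1_size + cfg$set2_size + 2L) {
    stop_arg("not enough filler protein-coding genes for planted sets")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic assignment of gene ids to roles in the synthetic study.
study_layout <- function(cfg) {
  regs <- default_regulators()
  n_lnc <- round(cfg$frac_lncrna * cfg$n_genes)
  n_fill_pcg <- cfg$n_genes - 43L - n_lnc
  pcg_ids <- sprintf("GENE%04d", seq_len(n_fill_pcg))
  lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))
  k <- cfg$n_clusters
  blocks <- split(lnc_ids[seq_len(k * cfg$marker_block)],
                  rep(seq_len(k), each = cfg$marker_block))
  names(blocks) <- paste0("C", seq_len(k))
  # one m6A writer/reader drives each marker block (shares its shift and
  # noise so the markers are CEGs of that regulator); erasers and the pure
  # correlation-pair regulators are kept out of the driver rotation
  driver_pool <- c("METTL3", "YTHDF1", "IGF2BP2", "VIRMA", "YTHDC1",
                   "WTAP", "HNRNPC", "RBM15")
  drivers <- rep_len(driver_pool, k)
  set1 <- pcg_ids[seq_len(cfg$set1_size)]
  set2 <- pcg_ids[cfg$set1_size + seq_len(cfg$set2_size)]
  pure_targets <- pcg_ids[cfg$set1_size + cfg$set2_size + 1:2]
  corr_pairs <- data.frame(target = pure_targets,
                           regulator = c("METTL16", "RBM15B"),
                           rho = cfg$corr_strength,
                           stringsAsFactors = FALSE)
  list(regulators = regs, pcg_ids = pcg_ids, lnc_ids = lnc_ids,
       marker_blocks = blocks, block_drivers = drivers,
       set1 = set1, set2 = set2, corr_pairs = corr_pairs,
       emd_cluster = paste0("C", k))
}

#' Generate the synthetic gene annotation
#'
#' Genes are tiled on one toy chromosome with 20 kb spacing so that the
#' +/- 3 kb promoter windows of neighbouring genes can never collide. The
#' 43 regulators come first (protein-coding), then filler protein-coding
#' genes, then lncRNAs (no CDS/3'UTR). Protein-coding genes get two exons,
#' a CDS and a strand-appropriate 3'UTR.
#'
#' @param cfg A [simulate_config()].
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(cfg) {
  lay <- study_layout(cfg)
  ids <- c(lay$regulators$regulator_id, lay$pcg_ids, lay$lnc_ids)
  biotype <- c(rep("protein_coding", 43L + length(lay$pcg_ids)),
               rep("lncRNA", length(lay$lnc_ids)))
  n <- length(ids)
  spacing <- 20000L
  with_seed(cfg$seed + 1L, {
    len <- sample(2500:8000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    l1 <- sample(300:800, n, replace = TRUE)
    l2 <- sample(400:900, n, replace = TRUE)
    u3 <- sample(150:300, n, replace = TRUE)
  })
  start <- 10000L + (seq_len(n) - 1L) * spacing
  end <- start + len
  exons <- cds <- utr3 <- vector("list", n)
  empty <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    s <- start[i]; e <- end[i]
    ex <- data.frame(start = c(s, e - l2[i]), end = c(s + l1[i], e))
    exons[[i]] <- ex
    if (biotype[i] == "protein_coding") {
      if (strand[i] == "-") {
        # 3' end is the left end of the body
        utr3[[i]] <- data.frame(start = s, end = s + u3[i])
        cds[[i]] <- data.frame(start = c(s + u3[i], e - l2[i]),
                               end = c(s + l1[i], e - 50L))
      } else {
        utr3[[i]] <- data.frame(start = e - u3[i], end = e)
        cds[[i]] <- data.frame(start = c(s + 50L, e - l2[i]),
                               end = c(s + l1[i], e - u3[i]))
      }
    } else {
      cds[[i]] <- empty
      utr3[[i]] <- empty
    }
  }
  out <- data.frame(gene_id = ids, biotype = biotype, chrom = "chrS",
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  out$tss <- ifelse(out$strand == "-", out$end - 1L, out$start)
  out$exons <- exons
  out$cds <- cds
  out$utr3 <- utr3
  gene_annotation(out)
}

#' Default site/DEG planting map of the synthetic study
#'
#' Histone sites (with matching cell-line DEGs) are planted in the
#' promoters of a subset of set1 (up) and set2 (down) genes, plus two
#' deliberately direction-discordant genes that must not yield criterion-1
#' evidence. m6A sites are planted in the transcribed region of every
#' lncRNA cluster marker (these are the intended EMRLs) and of a few set1
#' genes.
#'
#' @param cfg A [simulate_config()].
#' @return data.frame(gene_id, mod_type, sign, in_promoter, cell_line,
#'   concordant).
#' @export
default_planting <- function(cfg) {
  lay <- study_layout(cfg)
  hist_lines <- c("SNU719", "NCC24", "YCC10")
  m6a_lines <- c("AGS", "BGC823", "SGC7901")
  hist_mods <- c("H3K4me1", "H3K4me3", "H3K27ac")
  up <- lay$set1[seq_len(min(6L, length(lay$set1)))]
  dn <- lay$set2[seq_len(min(4L, length(lay$set2)))]
  disc <- lay$pcg_ids[length(lay$pcg_ids) - 0:1]  # discordant decoys
  hist_genes <- c(up, dn, disc)
  nh <- length(hist_genes)
  hist_df <- data.frame(
    gene_id = hist_genes,
    mod_type = rep_len(hist_mods, nh),
    sign = c(rep(1, length(up)), rep(-1, length(dn)), rep(1, length(disc))),
    in_promoter = TRUE,
    cell_line = rep_len(hist_lines, nh),
    concordant = c(rep(TRUE, length(up) + length(dn)), rep(FALSE, length(disc))),
    stringsAsFactors = FALSE
  )
  m6a_genes <- c(unlist(lay$marker_blocks, use.names = FALSE),
                 lay$set1[seq_len(min(3L, length(lay$set1)))])
  m6a_df <- data.frame(
    gene_id = m6a_genes,
    mod_type = "m6A",
    sign = 1,
    in_promoter = FALSE,
    cell_line = rep_len(m6a_lines, length(m6a_genes)),
    concordant = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(hist_df, m6a_df)
}

#' Generate modification-site tables
#'
#' Planted sites are placed inside the +/- 3 kb promoter window (histone
#' marks, or m6A with `in_promoter = TRUE`) or inside the gene's 3'UTR
#' (falling back to an exon when absent, e.g. lncRNAs), with
#' `|fold_change| > 1` and `p < 0.05`. Background sites are placed in the
#' intergenic gaps with sub-threshold fold-changes, so none of them pass
#' the differential-site filter.
#'
#' @param cfg A [simulate_config()].
#' @param genes A [gene_annotation()].
#' @param planted Planting map as from [default_planting()].
#' @return data.frame of sites sorted by (chrom, start), with `mod_type`
#'   and `cell_line` columns.
#' @export
simulate_sites <- function(cfg, genes, planted = default_planting(cfg)) {
  missing_genes <- setdiff(planted$gene_id, genes$gene_id)
  if (length(missing_genes)) {
    stop_arg("planted gene(s) absent from annotation: %s",
             paste(missing_genes, collapse = ", "))
  }
  with_seed(cfg$seed + 2L, {
    rows <- vector("list", nrow(planted))
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      j <- match(p$gene_id, genes$gene_id)
      g <- genes[j, , drop = FALSE]
      if (p$in_promoter) {
        off <- sample(-2600:2200, 1)
        s0 <- g$tss + off
        width <- 400L
      } else {
        reg <- g$utr3[[1]]
        if (nrow(reg) == 0) {
          ex <- g$exons[[1]]
          reg <- ex[nrow(ex), , drop = FALSE]  # fallback: last exon
        }
        len <- reg$end[1] - reg$start[1]
        width <- min(200L, len)
        s0 <- reg$start[1] + sample(0:(len - width), 1)
      }
      rows[[i]] <- data.frame(
        chrom = g$chrom, start = as.integer(s0), end = as.integer(s0 + width),
        strand = g$strand, mod_type = p$mod_type,
        fold_change = p$sign * runif(1, 1.5, 3),
        p_value = runif(1, 1e-5, 0.04),
        cell_line = p$cell_line, stringsAsFactors = FALSE
      )
    }
    bg <- cfg$n_background_sites
    if (bg > 0) {
      gi <- sample(seq_len(nrow(genes)), bg, replace = TRUE)
      off <- sample(11000:16500, bg, replace = TRUE)
      s0 <- 10000L + (gi - 1L) * 20000L + off
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chrS", start = s0, end = s0 + 300L,
        strand = ".", mod_type = sample(mod_types(), bg, replace = TRUE),
        fold_change = runif(bg, -0.9, 0.9),
        p_value = runif(bg, 0.001, 1),
        cell_line = sample(c("SNU719", "NCC24", "YCC10", "AGS", "BGC823",
                             "SGC7901"), bg, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate the synthetic expression matrix
#'
#' Samples are split evenly across `n_clusters` planted clusters; the last
#' cluster is EMD-like: `+effect_size` on set1 genes and FTO,
#' `-effect_size` on set2 genes and HDAC1. Each cluster additionally has
#' its own lncRNA marker block (`+effect_size` within the cluster) whose
#' genes share noise with a driving m6A writer/reader at correlation
#' `corr_strength`, and two shift-free gene-regulator pairs are planted at
#' the same correlation. Gaussian noise with SD `noise_sd` is added
#' throughout; with `effect_size = 0` and `corr_strength = 0` the matrix
#' is an exchangeable null.
#'
#' @param cfg A [simulate_config()].
#' @param genes A [gene_annotation()].
#' @return An [expr_dataset()] whose `samples` carry the planted `cluster`
#'   labels (`C1` ... `Ck`).
#' @export
simulate_expression <- function(cfg, genes) {
  lay <- study_layout(cfg)
  ids <- genes$gene_id
  n_g <- length(ids)
  n_s <- cfg$n_samples
  k <- cfg$n_clusters
  cluster <- sort(rep_len(seq_len(k), n_s))
  eff <- cfg$effect_size
  delta <- matrix(0, n_g, k, dimnames = list(ids, NULL))
  for (b in seq_len(k)) {
    delta[lay$marker_blocks[[b]], b] <- eff
    delta[lay$block_drivers[b], b] <-
      delta[lay$block_drivers[b], b] + 0.6 * eff
  }
  delta[lay$set1, k] <- delta[lay$set1, k] + eff
  delta[lay$set2, k] <- delta[lay$set2, k] - eff
  delta["FTO", k] <- delta["FTO", k] + eff
  delta["HDAC1", k] <- delta["HDAC1", k] - eff
  with_seed(cfg$seed + 3L, {
    base <- runif(n_g, 4, 10)
    noise <- matrix(rnorm(n_g * n_s, 0, cfg$noise_sd), n_g, n_s,
                    dimnames = list(ids, NULL))
    rho <- cfg$corr_strength
    if (rho > 0) {
      mix <- function(target, source) {
        noise[target, ] <<- rho * noise[source, ] +
          sqrt(1 - rho^2) * noise[target, ]
      }
      for (b in seq_len(k)) {
        for (m in lay$marker_blocks[[b]]) mix(m, lay$block_drivers[b])
      }
      for (i in seq_len(nrow(lay$corr_pairs))) {
        mix(lay$corr_pairs$target[i], lay$corr_pairs$regulator[i])
      }
    }
  })
  values <- base + delta[, cluster, drop = FALSE] + noise
  colnames(values) <- sprintf("S%03d", seq_len(n_s))
  samples <- data.frame(sample_id = colnames(values), cohort = "SIM",
                        cluster = paste0("C", cluster),
                        stringsAsFactors = FALSE)
  expr_dataset(values, samples)
}

#' Planted per-sample score of the synthetic study
#'
#' Evenly spaced cluster levels on \[-1, 1\] with the EMD-like cluster at
#' the top; drives the planted survival hazard and response probability.
#'
#' @param cfg A [simulate_config()].
#' @param cluster Character cluster labels (`C1` ...).
#' @return Numeric score per sample.
#' @export
planted_score <- function(cfg, cluster) {
  lev <- seq(-1, 1, length.out = cfg$n_clusters)
  lev[as.integer(sub("^C", "", cluster))]
}

#' Generate survival and ICI-response fields
#'
#' Survival times are exponential with log-hazard
#' `log(log(2)/baseline_median_os) + hazard_coef * z(score)`; censoring is
#' independent uniform on (30, `censor_max`) days. Observed times of 30
#' days or less are resampled, mirroring the study-design exclusion of
#' patients surviving less than 30 days. Responder probability is a
#' decreasing logistic function of the standardized score.
#'
#' @param cfg A [simulate_config()].
#' @param score Per-sample real score (any scale; standardized internally).
#' @return data.frame(os_time, os_event, ici_response).
#' @export
simulate_clinical <- function(cfg, score) {
  if (!is.finite(cfg$hazard_coef)) stop_arg("hazard_coef must be finite")
  n <- length(score)
  z <- if (sd(score) > 0) (score - mean(score)) / sd(score) else rep(0, n)
  rate <- log(2) / cfg$baseline_median_os * exp(cfg$hazard_coef * z)
  with_seed(cfg$seed + 4L, {
    tt <- rexp(n, rate)
    cc <- runif(n, 30, cfg$censor_max)
    obs <- pmin(tt, cc)
    for (iter in seq_len(1000)) {
      bad <- which(obs <= 30)
      if (!length(bad)) break
      tt[bad] <- rexp(length(bad), rate[bad])
      cc[bad] <- runif(length(bad), 30, cfg$censor_max)
      obs[bad] <- pmin(tt[bad], cc[bad])
    }
    p_resp <- stats::plogis(-0.4 - cfg$response_slope * z)
    resp <- ifelse(rbinom(n, 1, p_resp) == 1, "responder", "non_responder")
  })
  data.frame(os_time = obs, os_event = as.integer(tt <= cc),
             ici_response = resp, stringsAsFactors = FALSE)
}

# probability of joint mutation under given marginals and odds ratio
# (Plackett construction)
or_joint_p11 <- function(pa, pb, or) {
  if (or == 1) return(pa * pb)
  a <- or - 1
  s <- 1 + (pa + pb) * a
  (s - sqrt(s^2 - 4 * or * a * pa * pb)) / (2 * a)
}

#' Generate the binary mutation matrix
#'
#' Mutations are drawn over the 43 regulator genes with background
#' probability `mut_rate`; each configured co-mutation pair is drawn from
#' the joint 2x2 distribution with the configured odds ratio and the same
#' marginals.
#'
#' @param cfg A [simulate_config()].
#' @param sample_ids Character vector of sample ids.
#' @return Binary samples x genes matrix.
#' @export
simulate_mutations <- function(cfg, sample_ids) {
  genes <- default_regulators()$regulator_id
  n <- length(sample_ids)
  with_seed(cfg$seed + 5L, {
    m <- matrix(rbinom(n * length(genes), 1, cfg$mut_rate), n,
                dimnames = list(sample_ids, genes))
    cp <- cfg$comut_pairs
    for (i in seq_len(nrow(cp))) {
      pa <- pb <- cfg$mut_rate
      p11 <- or_joint_p11(pa, pb, cp$odds_ratio[i])
      probs <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
      cat4 <- sample.int(4, n, replace = TRUE, prob = probs)
      m[, cp$gene_a[i]] <- as.integer(cat4 %in% c(1L, 2L))
      m[, cp$gene_b[i]] <- as.integer(cat4 %in% c(1L, 3L))
    }
  })
  m
}

#' Generate per-cell-line differential-expression tables
#'
#' Emits one passing DEG record per planted histone site in its cell line,
#' with the log2 fold-change matching the site's direction when the
#' planting is concordant and opposing it otherwise (so discordant decoys
#' never yield criterion-1 evidence), plus sub-threshold background rows.
#'
#' @param cfg A [simulate_config()].
#' @param genes A [gene_annotation()].
#' @param planted Planting map as from [default_planting()].
#' @return data.frame(cell_line, gene_id, log2fc, p_value, p_adj).
#' @export
simulate_celline_deg <- function(cfg, genes, planted = default_planting(cfg)) {
  hist <- planted[planted$mod_type != "m6A", , drop = FALSE]
  with_seed(cfg$seed + 6L, {
    dir <- ifelse(hist$concordant, hist$sign, -hist$sign)
    fg <- data.frame(cell_line = hist$cell_line, gene_id = hist$gene_id,
                     log2fc = dir * runif(nrow(hist), 1.2, 2.5),
                     p_value = runif(nrow(hist), 1e-5, 0.01),
                     stringsAsFactors = FALSE)
    others <- setdiff(genes$gene_id, hist$gene_id)
    bg_genes <- sample(others, min(30L, length(others)))
    bg <- data.frame(cell_line = sample(unique(hist$cell_line),
                                        length(bg_genes), replace = TRUE),
                     gene_id = bg_genes,
                     log2fc = runif(length(bg_genes), -0.8, 0.8),
                     p_value = runif(length(bg_genes), 0.1, 1),
                     stringsAsFactors = FALSE)
  })
  out <- rbind(fg, bg)
  out$p_adj <- pmin(1, out$p_value * 2)
  rownames(out) <- NULL
  out
}

#' Generate the complete synthetic study
#'
#' Runs every generator with one configuration and packages the results
#' together with the planted truth (clusters, signature sets, intended
#' EMRLs, correlation pairs, per-sample score).
#'
#' @param cfg A [simulate_config()].
#' @return List with elements `annotation`, `sites` (all), `dhms`, `mms`,
#'   `celline_deg`, `expr` (an [expr_dataset()] with clinical fields and
#'   mutations attached), and `truth`.
#' @export
simulate_study <- function(cfg = simulate_config()) {
  genes <- simulate_annotation(cfg)
  lay <- study_layout(cfg)
  planted <- default_planting(cfg)
  sites <- simulate_sites(cfg, genes, planted)
  expr <- simulate_expression(cfg, genes)
  score <- planted_score(cfg, expr$samples$cluster)
  clin <- simulate_clinical(cfg, score)
  expr$samples <- cbind(expr$samples, clin)
  expr$mutations <- simulate_mutations(cfg, expr$samples$sample_id)
  deg <- simulate_celline_deg(cfg, genes, planted)
  truth <- list(
    cluster = expr$samples$cluster,
    emd_cluster = lay$emd_cluster,
    set1 = c(lay$set1, lay$marker_blocks[[lay$emd_cluster]]),
    set2 = lay$set2,
    marker_blocks = lay$marker_blocks,
    emrls = unlist(lay$marker_blocks, use.names = FALSE),
    corr_pairs = lay$corr_pairs,
    comut_pairs = cfg$comut_pairs,
    score = score,
    planted_sites = planted
  )
  list(annotation = genes, sites = sites,
       dhms = sites[sites$mod_type != "m6A", , drop = FALSE],
       mms = sites[sites$mod_type == "m6A", , drop = FALSE],
       celline_deg = deg, expr = expr, truth = truth)
}

#' Write a simulated study to a fixture directory
#'
#' Emits the GTF, the DHMS/MMS site tables, the expression matrix, the
#' clinical table, the mutation matrix, the per-cell-line DEG table and a
#' truth JSON with the planted labels and parameters. All files are
#' plain-text and byte-deterministic for a given configuration.
#'
#' @param study As from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(study$annotation, file.path(dir, "annotation.gtf"))
  write_site_table(study$dhms, file.path(dir, "dhms.tsv"))
  write_site_table(study$mms, file.path(dir, "mms.tsv"))
  write_expression_tsv(study$expr$values, file.path(dir, "expression.tsv"))
  write_tsv(study$expr$samples, file.path(dir, "clinical.tsv"))
  write_mutation_tsv(study$expr$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(study$celline_deg, file.path(dir, "celline_deg.tsv"))
  truth <- study$truth
  truth$planted_sites <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
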