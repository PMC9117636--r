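named_matrix <- function(nr, nc, data) {
  matrix(data, nr, nc, dimnames = list(sprintf("g%03d", seq_len(nr)),
                                       sprintf("s%03d", seq_len(nc))))
}

test_that("differential expression matches t.test and is antisymmetric", {
  set.seed(5)
  x <- named_matrix(50, 24, rnorm(50 * 24))
  x["g001", ] <- 5                       # flat gene
  x["g002", 1:12] <- x["g002", 1:12] + 2 # planted shift +2
  a <- colnames(x)[1:12]; b <- colnames(x)[13:24]
  de <- differential_expression(x, a, b)

  expect_equal(de$log2fc[de$gene_id == "g001"], 0)
  expect_equal(de$p_value[de$gene_id == "g001"], 1)
  expect_false(de$passes[de$gene_id == "g001"])
  expect_true(de$passes[de$gene_id == "g002"])

  # agrees with stats::t.test gene by gene
  for (g in c("g002", "g010", "g030")) {
    tt <- t.test(x[g, a], x[g, b])
    i <- de$gene_id == g
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }

  swap <- differential_expression(x, b, a)
  expect_equal(swap$log2fc, -de$log2fc)
  expect_equal(swap$p_value, de$p_value)

  expect_error(differential_expression(x, a, c(b, a[1])), "overlap")
  expect_error(differential_expression(x, a[1:2], b), ">= 3")
})

test_that("BH adjustment is monotone in p rank and bounded by 1", {
  set.seed(6)
  x <- named_matrix(200, 20, rnorm(4000))
  de <- differential_expression(x, colnames(x)[1:10], colnames(x)[11:20])
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-12))
  expect_true(all(de$p_adj <= 1))
  expect_equal(de$p_adj, p.adjust(de$p_value, "BH"))
})

test_that("regulator correlation screen flags planted CEGs, not null genes", {
  regs <- default_regulators()
  set.seed(7)
  n <- 200
  ids <- c(regs$regulator_id, "TARGET", sprintf("NULL%02d", 1:20))
  x <- matrix(rnorm(length(ids) * n), length(ids), n,
              dimnames = list(ids, sprintf("s%03d", 1:n)))
  x["TARGET", ] <- 0.8 * x["METTL3", ] + sqrt(1 - 0.64) * x["TARGET", ]
  cc <- correlate_with_regulators(x, c("TARGET", sprintf("NULL%02d", 1:20)))
  expect_true("TARGET" %in% ceg_genes(cc))
  hit <- cc[cc$gene_id == "TARGET" & cc$regulator_id == "METTL3", ]
  expect_gt(hit$rho, 0.6); expect_lt(hit$rho, 0.95)
  # family-wise: few null genes flagged
  expect_lt(length(intersect(ceg_genes(cc), sprintf("NULL%02d", 1:20))), 3)
  # self-correlation is exact
  x2 <- rbind(x, SELF = x["METTL3", ])
  cc2 <- correlate_with_regulators(x2, "SELF")
  expect_equal(cc2$rho[cc2$regulator_id == "METTL3"], 1)
})

test_that("regulator co-expression excludes self pairs and finds planted blocks", {
  regs <- default_regulators()
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(43 * n), 43, n,
              dimnames = list(regs$regulator_id, sprintf("s%03d", 1:n)))
  block <- c("SETD1A", "KMT2A", "METTL3")
  shared <- rnorm(n)
  for (g in block) x[g, ] <- sqrt(0.5) * shared + sqrt(0.5) * x[g, ]
  co <- regulator_coexpression(x)
  expect_false(any(co$gene_a == co$gene_b))
  expect_equal(nrow(co), choose(43, 2))
  inblock <- co$gene_a %in% block & co$gene_b %in% block
  expect_true(all(co$sig[inblock]))
  # duplicated regulator expression gives rho 1 and a flag
  x2 <- x; x2["HDAC2", ] <- x2["HDAC1", ]
  co2 <- regulator_coexpression(x2)
  dup <- co2[co2$gene_a == "HDAC1" & co2$gene_b == "HDAC2", ]
  expect_equal(dup$rho, 1)
  expect_true(dup$sig)
})

test_that("co-mutation test matches the exact enumeration oracle", {
  # hand example: perfectly co-occurring pair, p = 2 / choose(20, 10)
  m <- cbind(A = rep(c(1, 0), each = 10), B = rep(c(1, 0), each = 10))
  rownames(m) <- sprintf("s%02d", 1:20)
  res <- comutation_test(m)
  expect_equal(res$direction, "co_occurrence")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$p_value < 0.05)

  anti <- cbind(A = rep(c(1, 0), each = 10), B = rep(c(0, 1), each = 10))
  rownames(anti) <- sprintf("s%02d", 1:20)
  expect_equal(comutation_test(anti)$direction, "mutual_exclusivity")

  degen <- cbind(A = rep(1, 8), B = rep(c(1, 0), 4))
  rownames(degen) <- sprintf("s%02d", 1:8)
  rd <- comutation_test(degen)
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)

  # random tables with n <= 30 agree with the full-enumeration oracle exactly
  set.seed(9)
  for (r in 1:200) {
    n <- sample(4:30, 1)
    mm <- matrix(rbinom(2 * n, 1, runif(1, 0.2, 0.8)), n,
                 dimnames = list(sprintf("s%02d", 1:n), c("A", "B")))
    res <- comutation_test(mm)
    if (res$degenerate) next
    expect_equal(res$p_value,
                 oracle_fisher2x2(res$n11, res$n10, res$n01, res$n00),
                 tolerance = 1e-12)
    expect_equal(res$n11 + res$n10 + res$n01 + res$n00, n)
  }
})

test_that("cox screen recovers a planted hazard and excludes constants", {
  cfg <- simulate_config(seed = 12, n_samples = 500, hazard_coef = 1)
  set.seed(12)
  score <- rnorm(500)
  clin <- simulate_clinical(cfg, score)
  z <- (score - mean(score)) / sd(score)
  x <- rbind(score = z, flat = rep(1, 500),
             noise = rnorm(500))
  colnames(x) <- sprintf("s%03d", 1:500)
  expect_warning(
    res <- cox_screen(x, c("score", "flat", "noise"), alpha = 0.01,
                      os_time = clin$os_time, os_event = clin$os_event),
    "constant")
  expect_false("flat" %in% res$gene_id)
  expect_true(res$passes[res$gene_id == "score"])
  expect_lt(abs(res$coef[res$gene_id == "score"] - 1), 0.25)

  # the reported coefficient maximizes the Breslow partial likelihood:
  # a brute-force grid around it finds no better value
  bres_loglik <- function(beta, time, event, xv) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      d <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(xv[d]) * beta -
        length(d) * log(sum(exp(beta * xv[risk])))
    }
    ll
  }
  small <- 1:60
  fit <- cox_screen(x[, small], "score", os_time = clin$os_time[small],
                    os_event = clin$os_event[small])
  b <- fit$coef
  ll0 <- bres_loglik(b, clin$os_time[small], clin$os_event[small], z[small])
  for (db in c(-0.05, -0.01, 0.01, 0.05)) {
    expect_lt(bres_loglik(b + db, clin$os_time[small], clin$os_event[small],
                          z[small]), ll0 + 1e-9)
  }
})
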