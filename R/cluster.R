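# greedy maximin (spread-maximizing) k-means seeding: first centre drawn
# from the RNG stream, each further centre is the point farthest from the
# centres chosen so far
maximin_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    idx[j + 1L] <- which.max(d)
    d2 <- rowSums((x - matrix(x[idx[j + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d <- pmin(d, d2)
  }
  x[idx, , drop = FALSE]
}

kmeans_restarts <- function(x, k, restarts = 10L, iter_max = 50L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- maximin_centers(x, k)
    fit <- tryCatch(
      kmeans(x, centers = centers, iter.max = iter_max),
      error = function(e) NULL)
    if (is.null(fit)) fit <- kmeans(x, centers = k, iter.max = iter_max,
                                    nstart = 1)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Consensus clustering of samples by resampled k-means
#'
#' For each k in `k_range`, repeatedly subsamples `item_frac` of the
#' samples, runs Euclidean k-means (greedy spread-maximizing seeding, 10
#' restarts, best inertia kept), and records for every sample pair how
#' often they co-cluster among the resamples in which both were drawn.
#' Feature rows are z-scored before clustering. Final labels per k come
#' from average-linkage hierarchical clustering of 1 - consensus; k is
#' chosen by minimum PAC (proportion of ambiguous clustering, consensus
#' entries in (0.1, 0.9)) unless fixed with `fix_k` (the gastric-cancer
#' analysis fixes k = 4).
#'
#' @param x Features x samples matrix (e.g. expression restricted to the
#'   screened EMRLs) or an [expr_dataset()].
#' @param k_range Candidate cluster numbers (default 2:7, i.e. maxK = 7).
#' @param n_resamples Resampling iterations per k (default 1000).
#' @param item_frac Fraction of samples drawn per resample (default 0.8).
#' @param seed Integer seed; the run is deterministic given it.
#' @param fix_k Optional fixed number of clusters for the reported labels.
#' @return List of class `consensus_result`: `k_range`,
#'   `consensus_matrices` (per k, samples x samples in \[0,1\]), `labels`
#'   (per k), `pac` (per k), `chosen_k`, `labels_chosen`.
#' @export
consensus_cluster <- function(x, k_range = 2:7, n_resamples = 1000L,
                              item_frac = 0.8, seed = 1L, fix_k = NULL) {
  values <- get_values(x)
  n <- ncol(values)
  if (n < max(k_range) * 3) stop_arg("need at least 3 samples per cluster")
  keep <- apply(values, 1, sd) > 0
  z <- (values[keep, , drop = FALSE] -
          rowMeans(values[keep, , drop = FALSE])) /
    apply(values[keep, , drop = FALSE], 1, sd)
  xs <- t(z)  # samples x features
  m <- max(2L, ceiling(item_frac * n))
  res <- with_seed(seed, {
    lapply(k_range, function(k) {
      co <- matrix(0, n, n)
      cnt <- matrix(0, n, n)
      for (b in seq_len(n_resamples)) {
        idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
        fit <- kmeans_restarts(xs[idx, , drop = FALSE], k)
        cnt[idx, idx] <- cnt[idx, idx] + 1
        lab <- fit$cluster
        same <- outer(lab, lab, "==") * 1
        co[idx, idx] <- co[idx, idx] + same
      }
      if (any(cnt == 0)) {
        stop_arg("a sample pair was never co-sampled; increase n_resamples")
      }
      cons <- co / cnt
      diag(cons) <- 1
      dimnames(cons) <- list(colnames(values), colnames(values))
      cons
    })
  })
  names(res) <- as.character(k_range)
  labels <- lapply(seq_along(k_range), function(i) {
    hc <- hclust(stats::as.dist(1 - res[[i]]), method = "average")
    setNames(cutree(hc, k_range[i]), colnames(values))
  })
  names(labels) <- as.character(k_range)
  pac <- vapply(res, function(cons) {
    off <- cons[upper.tri(cons)]
    mean(off > 0.1 & off < 0.9)
  }, numeric(1))
  chosen_k <- if (!is.null(fix_k)) as.integer(fix_k)
              else k_range[which.min(pac)]
  if (!chosen_k %in% k_range) stop_arg("fix_k must be one of k_range")
  structure(list(k_range = k_range, consensus_matrices = res,
                 labels = labels, pac = pac, chosen_k = chosen_k,
                 labels_chosen = labels[[as.character(chosen_k)]]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, chosen k = %d\n",
              paste(x$k_range, collapse = ","), x$chosen_k))
  cat("PAC:", paste(sprintf("k=%s %.3f", names(x$pac), x$pac),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Designate the EMD cluster by survival
#'
#' The EMD (epigenetic-modification-dysregulated) cluster is the one with
#' the lowest Kaplan-Meier survival at the last time point common to all
#' clusters (i.e. the largest cumulative hazard); the reference cluster is
#' the best-survival one. Survival ties are broken by the larger mean
#' expression of the supplied up-signature genes, with a warning.
#'
#' @param labels Named cluster labels per sample (names = sample ids).
#' @param os_time,os_event Survival fields aligned with `labels`.
#' @param up_expr Optional matrix of up-signature EMRL expression (genes x
#'   samples) used only to break survival ties.
#' @return List: `emd` (label), `reference` (label), `surv_at_horizon`
#'   (per-cluster KM survival at the common horizon), `horizon`.
#' @export
label_emd_cluster <- function(labels, os_time, os_event, up_expr = NULL) {
  stopifnot(length(labels) == length(os_time))
  ok <- !is.na(os_time) & !is.na(os_event)
  labels_ok <- labels[ok]
  fit_surv_at <- function(group, t) {
    f <- survival::survfit(survival::Surv(os_time[ok][group],
                                          os_event[ok][group]) ~ 1)
    summary(f, times = t, extend = TRUE)$surv
  }
  horizon <- min(tapply(os_time[ok], labels_ok, max))
  levs <- sort(unique(labels_ok))
  surv <- vapply(levs, function(cl) {
    fit_surv_at(labels_ok == cl, horizon)
  }, numeric(1))
  names(surv) <- as.character(levs)
  worst <- names(surv)[surv == min(surv)]
  if (length(worst) > 1) {
    warning("survival tie between clusters; breaking by up-signature expression",
            call. = FALSE)
    if (!is.null(up_expr)) {
      mu <- vapply(worst, function(cl)
        mean(up_expr[, names(labels)[labels == cl], drop = FALSE]),
        numeric(1))
      worst <- worst[which.max(mu)]
    } else {
      worst <- worst[1]
    }
  }
  list(emd = worst[1], reference = names(surv)[which.max(surv)],
       surv_at_horizon = surv, horizon = horizon)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 for identical partitions (up to relabelling), ~0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
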