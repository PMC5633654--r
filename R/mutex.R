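#' Coverage of a gene set in a binary alteration matrix
#'
#' The coverage statistic is the number of samples altered in at least one
#' gene of the set. Under a fixed per-gene alteration count, mutually
#' exclusive alterations maximize coverage, so coverage above the
#' burden-respecting null signals exclusivity.
#'
#' @param calls binary genes x samples matrix (rownames = genes).
#' @param gene_set character vector of genes (subset of rownames).
#' @return Integer count of covered samples.
#' @export
coverage_statistic <- function(calls, gene_set) {
  if (length(gene_set) == 0L) stop("coverage_statistic: empty gene set")
  missing <- setdiff(gene_set, rownames(calls))
  if (length(missing))
    stop("coverage_statistic: genes not in matrix: ", paste(missing, collapse = ", "))
  sum(colSums(calls[gene_set, , drop = FALSE]) > 0L)
}

#' Weighted-permutation test for mutually exclusive alterations
#'
#' Compares the observed coverage of a gene set against a background of
#' `n_sims` simulations. Each simulation redraws, for every gene in the
#' set, its observed number of altered samples without replacement, with
#' selection probability proportional to each sample's total alteration
#' burden over all genes, so both the per-gene alteration counts and the
#' per-sample burden structure are respected. Mutual exclusivity is
#' signaled by observed coverage high relative to the null: the empirical
#' p-value is \eqn{(1 + \#\{cov_{sim} \ge cov_{obs}\}) / (n_{sims} + 1)},
#' and the Z score is \eqn{(obs - mean_{null}) / sd_{null}}.
#'
#' @param calls binary genes x samples alteration matrix.
#' @param gene_set genes to test.
#' @param n_sims number of simulations (default 1e5).
#' @param seed integer seed.
#' @param epsilon pseudo-burden assigned to zero-burden samples so they
#'   remain eligible (default 0.01).
#' @param chunk simulations per vectorized block (memory control).
#' @return An object of class `mutex_result`: `observed_coverage`,
#'   `null_mean`, `null_sd`, `z_score` (`NA` when the null is degenerate),
#'   `empirical_p`, `n_sims`, `n_samples`, `gene_set`.
#' @export
mutex_test <- function(calls, gene_set, n_sims = 100000L, seed = 1L,
                       epsilon = 0.01, chunk = 20000L) {
  obs <- coverage_statistic(calls, gene_set)
  n <- ncol(calls)
  burden <- colSums(calls)
  w <- ifelse(burden > 0, burden, epsilon)
  k <- rowSums(calls[gene_set, , drop = FALSE])
  if (any(k > n)) stop("mutex_test: per-gene alteration count exceeds sample count")
  set.seed(seed)
  cov_sim <- numeric(0)
  remaining <- n_sims
  while (remaining > 0L) {
    cs <- min(chunk, remaining)
    covered <- matrix(FALSE, cs, n)
    for (g in seq_along(k)) {
      kg <- k[g]
      if (kg == 0L) next
      # exponential race: the kg smallest of Exp(w_s) keys are a weighted
      # sample without replacement
      keys <- stats::rexp(cs * n) / rep(w, each = cs)
      dim(keys) <- c(cs, n)
      for (d in seq_len(kg)) {
        j <- max.col(-keys, ties.method = "first")
        covered[cbind(seq_len(cs), j)] <- TRUE
        keys[cbind(seq_len(cs), j)] <- Inf
      }
    }
    cov_sim <- c(cov_sim, rowSums(covered))
    remaining <- remaining - cs
  }
  null_mean <- mean(cov_sim)
  null_sd <- stats::sd(cov_sim)
  structure(list(observed_coverage = obs,
                 null_mean = null_mean, null_sd = null_sd,
                 z_score = if (null_sd > 0) (obs - null_mean) / null_sd else NA_real_,
                 empirical_p = (1 + sum(cov_sim >= obs)) / (n_sims + 1),
                 n_sims = n_sims, n_samples = n, gene_set = gene_set),
            class = "mutex_result")
}

#' @export
print.mutex_result <- function(x, ...) {
  cat(sprintf("<mutex_result> %d genes, %d samples: coverage %d (null %.2f +/- %.2f)\n",
              length(x$gene_set), x$n_samples, x$observed_coverage,
              x$null_mean, x$null_sd))
  cat(sprintf("  Z = %s, empirical P = %.4g (%d simulations)\n",
              ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score)),
              x$empirical_p, x$n_sims))
  invisible(x)
}

#' Run the mutual-exclusivity test per cancer-type stratum
#'
#' Runs [mutex_test()] for each named gene set within each sample stratum
#' (e.g. cancer type, to avoid tissue-related biases) and on the pooled
#' matrix. Strata with fewer than `min_stratum` samples are skipped with a
#' warning.
#'
#' @param calls binary genes x samples matrix.
#' @param gene_sets named list of gene vectors.
#' @param strata sample stratum labels (length = ncol), or `NULL` for
#'   pooled only.
#' @param n_sims,seed,epsilon as in [mutex_test()]; per-(set, stratum)
#'   seeds are derived deterministically from `seed`.
#' @param min_stratum minimum stratum size (default 5).
#' @return Data frame keyed by (`set`, `stratum`), with the
#'   `mutex_result` fields as columns and the result objects in attribute
#'   `"results"`.
#' @export
mutex_scan <- function(calls, gene_sets, strata = NULL, n_sims = 100000L,
                       seed = 1L, epsilon = 0.01, min_stratum = 5L) {
  stopifnot(length(gene_sets) >= 1L, !is.null(names(gene_sets)))
  groups <- list(pooled = seq_len(ncol(calls)))
  if (!is.null(strata)) {
    stopifnot(length(strata) == ncol(calls))
    for (st in unique(strata)) groups[[st]] <- which(strata == st)
  }
  rows <- list(); results <- list()
  i <- 0L
  for (set_name in names(gene_sets)) {
    for (st in names(groups)) {
      i <- i + 1L
      idx <- groups[[st]]
      if (length(idx) < min_stratum) {
        warning(sprintf("mutex_scan: stratum %s has %d < %d samples; skipped",
                        st, length(idx), min_stratum))
        next
      }
      res <- mutex_test(calls[, idx, drop = FALSE], gene_sets[[set_name]],
                        n_sims = n_sims, seed = seed + i, epsilon = epsilon)
      results[[paste(set_name, st, sep = "|")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, stratum = st, n_samples = length(idx),
        observed_coverage = res$observed_coverage, null_mean = res$null_mean,
        null_sd = res$null_sd, z_score = res$z_score,
        empirical_p = res$empirical_p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), stratum = character())
  attr(out, "results") <- results
  out
}
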