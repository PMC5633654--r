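# beta-binomial log density; mu in (0,1), s = precision (alpha+beta)
.dbetabinom_log <- function(m, n, mu, s) {
  a <- mu * s; b <- (1 - mu) * s
  lchoose(n, m) + lbeta(m + a, n - m + b) - lbeta(a, b)
}

#' Segment a methylome into hypomethylated regions (HMRs)
#'
#' Fits a two-state first-order hidden Markov model over the ordered CpG
#' sequence with beta-binomial emissions on the (methylated, total) read
#' counts, sharing parameters across chromosomes (each chromosome is an
#' independent chain). Parameters are fitted by Baum-Welch EM; the state
#' with the lower emission mean is the hypomethylated state. Per-CpG
#' posterior decoding (posterior > 0.5; optionally Viterbi) yields maximal
#' hypomethylated runs; runs are split where consecutive CpGs lie more than
#' `max_intra_gap_bp` apart, and runs with fewer than `min_cpgs` CpGs are
#' discarded. Each HMR spans its first CpG to its last CpG + 2 (half-open,
#' covering the CpG dinucleotide).
#'
#' Degenerate inputs (essentially constant methylation levels) bypass the
#' HMM: a uniformly methylated sample yields no HMRs, a uniformly
#' unmethylated sample yields one HMR per chromosome.
#'
#' @param sample a [methylome()].
#' @param min_cpgs minimum CpGs per HMR (default 10).
#' @param max_intra_gap_bp split HMRs across CpG gaps larger than this
#'   (default 5000), so calls never bridge unsequenced deserts.
#' @param seed integer seed (used for the perturbed EM restart).
#' @param decoding `"posterior"` (default) or `"viterbi"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return A data frame of class `hmr_set` with columns `chrom`, `start`,
#'   `end`, `n_cpg`, `mean_level`; fitted HMM parameters are attached as
#'   attribute `"fit"`.
#' @export
segment_hmrs <- function(sample, min_cpgs = 10L, max_intra_gap_bp = 5000L,
                         seed = 1L, decoding = c("posterior", "viterbi"),
                         tol = 1e-4, max_iter = 200L) {
  decoding <- match.arg(decoding)
  stopifnot(nrow(sample) > 0)
  set.seed(seed)
  chroms <- split(seq_len(nrow(sample)), sample$chrom)
  lv <- sample$level
  hypo_call <- NULL
  fit <- NULL
  if (max(lv) - min(lv) < 0.05) {
    # single-state data: classify globally by mean level
    hypo_call <- rep(mean(lv) < 0.5, nrow(sample))
  } else {
    fit <- .fit_bb_hmm(sample, chroms, tol, max_iter)
    if (is.null(fit)) {
      fit <- .fit_bb_hmm(sample, chroms, tol, max_iter, jitter = TRUE)
      if (is.null(fit)) stop("segment_hmrs: EM failed to converge on both starts")
    }
    hypo <- which.min(fit$mu)
    if (decoding == "posterior") {
      hypo_call <- fit$gamma[, hypo] > 0.5
    } else {
      hypo_call <- logical(nrow(sample))
      for (idx in chroms) {
        path <- viterbi_hmm(fit$logemit[idx, , drop = FALSE], fit$A, fit$pi)
        hypo_call[idx] <- path == hypo
      }
    }
  }
  out <- list()
  for (idx in chroms) {
    calls <- hypo_call[idx]
    if (!any(calls)) next
    pos <- sample$pos[idx]
    # break runs at state changes and at large CpG gaps
    gapbreak <- c(FALSE, diff(pos) > max_intra_gap_bp)
    run_id <- cumsum(c(TRUE, diff(calls) != 0) | gapbreak)
    for (r in split(seq_along(calls), run_id)) {
      if (!calls[r[1L]] || length(r) < min_cpgs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = sample$chrom[idx[1L]],
        start = pos[r[1L]],
        end = pos[r[length(r)]] + 2L,
        n_cpg = length(r),
        mean_level = mean(sample$level[idx][r]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpg = integer(), mean_level = numeric())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sample_id") <- attr(sample, "sample_id")
  attr(res, "fit") <- if (is.null(fit)) NULL else
    list(mu = fit$mu, s = fit$s, A = fit$A, pi = fit$pi, loglik = fit$loglik,
         iterations = fit$iterations)
  class(res) <- unique(c("hmr_set", class(res)))
  res
}

# Baum-Welch for the 2-state beta-binomial HMM; returns NULL on degeneracy
.fit_bb_hmm <- function(sample, chroms, tol, max_iter, jitter = FALSE) {
  m <- sample$meth; n <- sample$total; lv <- sample$level
  qs <- stats::quantile(lv, c(0.1, 0.9), names = FALSE)
  mu <- c(min(max(qs[1], 0.02), 0.45), min(max(qs[2], 0.55), 0.98))
  if (jitter) mu <- pmin(pmax(mu + stats::rnorm(2, 0, 0.05), 0.02), 0.98)
  s <- c(10, 10)
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  pi <- c(0.5, 0.5)
  ll_old <- -Inf
  iterations <- 0L
  gamma <- NULL; logemit <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    logemit <- cbind(.dbetabinom_log(m, n, mu[1], s[1]),
                     .dbetabinom_log(m, n, mu[2], s[2]))
    ll <- 0
    gamma <- matrix(0, length(m), 2)
    xi <- matrix(0, 2, 2)
    pi_acc <- c(0, 0)
    for (idx in chroms) {
      fb <- fb_hmm(logemit[idx, , drop = FALSE], A, pi)
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      pi_acc <- pi_acc + fb$gamma[1L, ]
      ll <- ll + fb$loglik
    }
    conv <- abs(ll - ll_old) < tol * (abs(ll_old) + 1)
    ll_old <- ll
    # M-step
    A <- xi / rowSums(xi)
    pi <- pi_acc / length(chroms)
    pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
    for (k in 1:2) {
      g <- gamma[, k]
      mu_k <- sum(g * m) / sum(g * n)
      mu[k] <- min(max(mu_k, 1e-4), 1 - 1e-4)
      opt <- stats::optimize(function(ls)
        -sum(g * .dbetabinom_log(m, n, mu[k], exp(ls))),
        interval = c(log(0.5), log(5000)))
      s[k] <- exp(opt$minimum)
    }
    if (conv) break
  }
  if (abs(mu[1] - mu[2]) < 1e-4) return(NULL)
  logemit <- cbind(.dbetabinom_log(m, n, mu[1], s[1]),
                   .dbetabinom_log(m, n, mu[2], s[2]))
  list(mu = mu, s = s, A = A, pi = pi, gamma = gamma, logemit = logemit,
       loglik = ll_old, iterations = iterations)
}

#' Summarize an HMR segmentation
#'
#' @param hmrs an `hmr_set` (or interval data frame).
#' @param genome_bp size in bp of the analyzed genome.
#' @return List with `n_hmrs`, `coverage_bp`, `coverage_pct` and
#'   `mean_size_geometric` (0 when there are no HMRs).
#' @export
summarize_segmentation <- function(hmrs, genome_bp) {
  stopifnot(genome_bp > 0)
  if (!nrow(hmrs))
    return(list(n_hmrs = 0L, coverage_bp = 0, coverage_pct = 0,
                mean_size_geometric = 0))
  widths <- as.numeric(hmrs$end - hmrs$start)
  list(n_hmrs = nrow(hmrs),
       coverage_bp = sum(widths),
       coverage_pct = 100 * sum(widths) / genome_bp,
       mean_size_geometric = exp(mean(log(widths))))
}

#' Classify HMRs as focal or PMD-like blocks
#'
#' Large HMRs at intermediate methylation mark partially methylated
#' domains (PMDs), the disordered blocks characteristic of cancer
#' methylomes, as opposed to focal regulatory hypomethylation.
#'
#' @param hmrs an `hmr_set` with `mean_level`.
#' @param size_cut_bp minimum width for a block (default 1500).
#' @param level_band numeric length-2: mean-level range (inclusive) for a
#'   block (default `c(0.3, 0.7)`).
#' @return Character vector, `"block"` or `"focal"`, one per HMR.
#' @export
classify_blocks <- function(hmrs, size_cut_bp = 1500L, level_band = c(0.3, 0.7)) {
  stopifnot(length(level_band) == 2L, level_band[1] <= level_band[2])
  if (!nrow(hmrs)) return(character(0))
  width <- hmrs$end - hmrs$start
  is_block <- width > size_cut_bp &
    hmrs$mean_level >= level_band[1] & hmrs$mean_level <= level_band[2]
  ifelse(is_block, "block", "focal")
}
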