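# Independent brute-force oracles used across the suite. Everything here is
# deliberately naive (per-base boolean arrays, double loops, exhaustive
# enumeration) and never calls the code paths it checks.

# per-base boolean coverage of a single-chromosome interval set
bits_of <- function(x, len, chrom = "chr1") {
  v <- logical(len)
  x <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(x))) {
    s <- max(0L, x$start[i]); e <- min(len, x$end[i])
    if (s < e) v[(s + 1L):e] <- TRUE
  }
  v
}

# random interval set on one toy chromosome
random_intervals <- function(n, len, max_width = 500L, chrom = "chr1") {
  s <- sample.int(len - max_width, n)
  w <- sample.int(max_width, n)
  interval_set(rep(chrom, n), s, pmin(s + w, len))
}

# per-base oracle for gap-closing merge
oracle_merge_bits <- function(bits, max_gap) {
  idx <- which(bits)
  if (!length(idx)) return(bits)
  out <- bits
  if (length(idx) > 1L) {
    gaps <- diff(idx)
    for (i in which(gaps > 1L & gaps <= max_gap + 1L))
      out[(idx[i] + 1L):(idx[i + 1L] - 1L)] <- TRUE
  }
  out
}

# base-level Jaccard between two interval sets
jaccard_bp <- function(a, b) {
  inter <- total_bp(intersect_intervals(a, b))
  uni <- total_bp(a) + total_bp(b) - inter
  if (uni == 0) return(NA_real_)
  inter / uni
}

# small methylome straight from vectors
mk_methylome <- function(pos, meth, total, chrom = "chr1", id = "s1",
                         tissue = "t1", status = "normal") {
  methylome(data.frame(chrom = chrom, pos = pos, meth = meth, total = total),
            sample_id = id, tissue = tissue, status = status)
}

# minimal smoothed-profile-shaped frame for the DMR caller
mk_profile <- function(pos, level, half, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, level_hat = level,
             ci_low = pmax(0, level - half), ci_high = pmin(1, level + half),
             window_bp = 0L)
}

# probability of drawing the unordered subset `sub` (indices) in successive
# weighted draws without replacement, weights w
subset_prob_wor <- function(sub, w) {
  k <- length(sub)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  tot <- sum(w)
  p <- 0
  for (ord in perms(sub)) {
    rem <- tot; pr <- 1
    for (j in ord) { pr <- pr * w[j] / rem; rem <- rem - w[j] }
    p <- p + pr
  }
  p
}

# exact null distribution of the coverage statistic under the weighted
# without-replacement model, by exhaustive enumeration over per-gene subsets
oracle_mutex_pvalue <- function(calls, gene_set, epsilon = 0.01) {
  n <- ncol(calls)
  burden <- colSums(calls)
  w <- ifelse(burden > 0, burden, epsilon)
  ks <- rowSums(calls[gene_set, , drop = FALSE])
  obs <- sum(colSums(calls[gene_set, , drop = FALSE]) > 0)
  per_gene <- lapply(ks, function(k) {
    if (k == 0) return(list(list(sub = integer(0), p = 1)))
    subs <- utils::combn(n, k, simplify = FALSE)
    lapply(subs, function(s) list(sub = s, p = subset_prob_wor(s, w)))
  })
  p_ge <- 0
  rec <- function(g, covered, p_acc) {
    if (p_acc == 0) return()
    if (g > length(per_gene)) {
      if (sum(covered) >= obs) p_ge <<- p_ge + p_acc
      return()
    }
    for (e in per_gene[[g]]) {
      cov2 <- covered
      cov2[e$sub] <- TRUE
      rec(g + 1L, cov2, p_acc * e$p)
    }
  }
  rec(1L, logical(n), 1)
  list(p = unname(p_ge), observed = obs)
}

# two-sided Fisher p by direct hypergeometric summation on a 2x2 table
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(x_obs, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_index <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - exp_index) / (max_index - exp_index)
}
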