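test_that("identical tissue sets give full common coverage and no t-HMRs", {
  x <- interval_set(c("chr1", "chr1"), c(100L, 5000L), c(900L, 6200L))
  cat2 <- build_catalog(list(a = x, b = x))
  expect_equal(total_bp(cat2$c_hmrs), total_bp(x))
  expect_equal(nrow(cat2$t_hmrs$a), 0L)
  expect_equal(nrow(cat2$t_hmrs$b), 0L)
  expect_equal(nrow(cat2$frequent_hmrs), 0L)
})

test_that("disjoint tissue sets give no common and all tissue-specific HMRs", {
  a <- interval_set("chr1", 100L, 900L)
  b <- interval_set("chr1", 5000L, 6200L)
  cat2 <- build_catalog(list(a = a, b = b))
  expect_equal(nrow(cat2$c_hmrs), 0L)
  expect_equal(total_bp(cat2$t_hmrs$a), total_bp(a))
  expect_equal(total_bp(cat2$t_hmrs$b), total_bp(b))
})

test_that("a single tissue is rejected", {
  expect_error(build_catalog(list(a = interval_set("chr1", 0L, 10L))),
               ">= 2 tissues")
})

test_that("the planted 8-tissue design is partitioned exactly", {
  d <- genome_design(seed = 55, n_chromosomes = 1L, chromosome_bp = 2e6,
                     n_c = 8L, n_frequent = 4L, n_t_per_tissue = 3L,
                     n_null = 4L)
  cat8 <- build_catalog(d$planted)
  expect_equal(jaccard_bp(cat8$c_hmrs, d$planted_kind$c_hmrs), 1.0)
  expect_equal(jaccard_bp(cat8$frequent_hmrs, d$planted_kind$frequent_hmrs), 1.0)
  for (t in d$tissues)
    expect_equal(total_bp(intersect_intervals(cat8$t_hmrs[[t]],
                                              d$planted_kind$t_hmrs[[t]])),
                 total_bp(d$planted_kind$t_hmrs[[t]]))
  # remainder accounting: every island is c, frequent, t or absent
  n_unique <- nrow(d$islands[d$islands$kind != "null", ])
  expect_equal(nrow(cat8$c_hmrs) + nrow(cat8$frequent_hmrs) +
                 sum(vapply(cat8$t_hmrs, nrow, 0L)),
               n_unique)
})

test_that("common-HMR intersection matches a per-base oracle", {
  set.seed(66)
  len <- 50000L
  sets <- lapply(1:4, function(i) random_intervals(12, len))
  names(sets) <- paste0("t", 1:4)
  cat4 <- build_catalog(sets, merge_gap_bp = 0L)
  expect_equal(bits_of(cat4$c_hmrs, len),
               Reduce(`&`, lapply(sets, bits_of, len = len)))
})

test_that("adding a tissue never grows common-HMR coverage", {
  set.seed(77)
  len <- 80000L
  sets <- lapply(1:5, function(i) random_intervals(15, len, max_width = 2000L))
  names(sets) <- paste0("t", 1:5)
  cov_k <- vapply(2:5, function(k)
    total_bp(build_catalog(sets[1:k])$c_hmrs), numeric(1))
  expect_true(all(diff(cov_k) <= 0))
})

test_that("co-activation is 1 everywhere when all promoters are open", {
  d <- genome_design(seed = 12, n_chromosomes = 1L, chromosome_bp = 1e6,
                     n_tissues = 3L, n_c = 2L, n_frequent = 2L,
                     n_t_per_tissue = 2L, n_null = 1L, frequent_tissues = 2L)
  cat3 <- build_catalog(d$planted)
  st <- matrix("hypomethylated", 3, nrow(d$promoters),
               dimnames = list(d$tissues, d$promoters$gene))
  m <- co_activation(cat3, d$promoters, st)
  expect_true(all(m == 1))
})

test_that("planted tissue-restricted promoter activity gives identity pattern", {
  d <- genome_design(seed = 13, n_chromosomes = 1L, chromosome_bp = 1e6,
                     n_tissues = 3L, n_c = 2L, n_frequent = 2L,
                     n_t_per_tissue = 3L, n_null = 1L, frequent_tissues = 2L)
  cat3 <- build_catalog(d$planted)
  st <- matrix("methylated", 3, nrow(d$promoters),
               dimnames = list(d$tissues, d$promoters$gene))
  # the t-HMR islands' own promoters are open only in the owning tissue
  for (t in d$tissues) {
    own <- d$islands$gene[!is.na(d$islands$tissue) & d$islands$tissue == t]
    st[t, own] <- "hypomethylated"
  }
  m <- co_activation(cat3, d$promoters, st)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m[upper.tri(m)] == 0) && all(m[lower.tri(m)] == 0))
})

test_that("composite profiles are flat for uniform methylomes", {
  pos <- seq(0L, by = 40L, length.out = 600L)
  m <- mk_methylome(pos, meth = rep(3L, 600), total = rep(4L, 600))
  hmrs <- interval_set("chr1", c(5000L, 15000L), c(6000L, 16000L))
  prof <- composite_profile(hmrs, list(m), flank_bp = 2000L, bin_bp = 4L)
  vals <- prof[!is.na(prof[, 1]), 1]
  expect_true(all(abs(vals - 0.75) < 1e-12))
})

test_that("a step methylome yields a centered well", {
  pos <- seq(0L, by = 20L, length.out = 1000L)
  hmr <- interval_set("chr1", 9000L, 11000L)
  meth <- ifelse(pos >= 9000L & pos < 11000L, 0L, 20L)
  m <- mk_methylome(pos, meth, rep(20L, 1000))
  prof <- composite_profile(hmr, list(m), flank_bp = 2000L, bin_bp = 100L)
  off <- attr(prof, "offset")
  expect_lt(max(prof[abs(off) < 900, 1], na.rm = TRUE), 0.01)
  expect_gt(min(prof[off < -1100, 1], na.rm = TRUE), 0.99)
  expect_gt(min(prof[off > 1100, 1], na.rm = TRUE), 0.99)
})

test_that("composite profile equals a direct per-bin oracle", {
  set.seed(14)
  pos <- sort(sample.int(200000L, 3000L))
  total <- 1L + stats::rpois(3000, 10)
  m <- mk_methylome(pos, stats::rbinom(3000, total, 0.5), total)
  st <- sort(sample.int(150000L, 10L)) + 1000L
  hmrs <- interval_set("chr1", st, st + 800L)
  flank <- 1000L; bin <- 50L
  prof <- composite_profile(hmrs, list(m), flank_bp = flank, bin_bp = bin)
  centers <- floor((hmrs$start + hmrs$end) / 2)
  breaks <- seq(-flank, flank, by = bin)
  acc <- rep(0, length(breaks) - 1L); cnt <- rep(0L, length(breaks) - 1L)
  for (cc in centers) {
    sel <- which(m$pos >= cc - flank & m$pos < cc + flank)
    b <- findInterval(m$pos[sel] - cc, breaks)
    for (j in seq_along(sel)) {
      acc[b[j]] <- acc[b[j]] + m$level[sel[j]]
      cnt[b[j]] <- cnt[b[j]] + 1L
    }
  }
  expected <- ifelse(cnt > 0, acc / cnt, NA_real_)
  expect_equal(unname(prof[, 1]), expected)
})

test_that("tiled Fisher enrichment matches count and hypergeometric oracles", {
  set.seed(15)
  universe <- interval_set("chr1", 0L, 40000L)
  query <- random_intervals(8, 40000L, max_width = 1500L)
  annot <- random_intervals(8, 40000L, max_width = 1500L)
  res <- interval_enrichment(query, annot, universe, tile_bp = 100L)
  # oracle: classify every tile midpoint with plain arithmetic
  mids <- seq(0L, 39900L, by = 100L) + 50L
  in_q <- vapply(mids, function(p) any(query$start <= p & p < query$end), TRUE)
  in_a <- vapply(mids, function(p) any(annot$start <= p & p < annot$end), TRUE)
  tab <- matrix(c(sum(in_q & in_a), sum(in_q & !in_a),
                  sum(!in_q & in_a), sum(!in_q & !in_a)), 2, 2, byrow = TRUE)
  expect_equal(unname(res$table), tab)
  expect_equal(res$p_value, oracle_fisher_p(tab), tolerance = 1e-8)
})

test_that("degenerate enrichment margins are flagged", {
  universe <- interval_set("chr1", 0L, 10000L)
  res <- interval_enrichment(interval_set("chr1", 0L, 2000L),
                             universe, universe)
  expect_true(res$degenerate)
  expect_true(is.na(res$odds_ratio))
  expect_error(interval_enrichment(interval_set(character(), integer(),
                                                integer()),
                                   universe, universe),
               "empty")
})
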