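# small hand-built summary: betas as given, one probe count per HMR
mk_summary <- function(mean_beta, n_probes, groups, labels = NULL) {
  ns <- ncol(mean_beta)
  if (is.null(labels)) labels <- groups
  if (is.null(colnames(mean_beta)))
    colnames(mean_beta) <- paste0("s", seq_len(ns))
  hmrs <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 1000L, length.out = nrow(mean_beta)),
                     end = seq(500L, by = 1000L, length.out = nrow(mean_beta)),
                     n_probes = n_probes,
                     represented = n_probes >= 1L)
  rownames(mean_beta) <- paste0(hmrs$chrom, ":", hmrs$start, "-", hmrs$end)
  structure(list(hmrs = hmrs, mean_beta = mean_beta,
                 samples = data.frame(sample_id = colnames(mean_beta),
                                      label = labels, group = groups,
                                      stringsAsFactors = FALSE)),
            class = "hmr_beta_summary")
}

test_that("probe-to-HMR means are computed over non-missing probes", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       chrom = "chr1", pos = c(100L, 200L, 300L, 5000L))
  beta <- matrix(c(0.1, 0.2, 0.3, 0.9), 4, 1)
  bm <- beta_matrix(beta, probes,
                    data.frame(sample_id = "s1", label = "colon",
                               group = "normal"))
  su <- hmr_beta_summary(interval_set("chr1", 0L, 1000L), bm, min_probes = 2L)
  expect_equal(su$hmrs$n_probes, 3L)
  expect_true(su$hmrs$represented)
  expect_equal(unname(su$mean_beta[1, 1]), 0.2)

  su1 <- hmr_beta_summary(interval_set("chr1", 4900L, 5100L), bm,
                          min_probes = 2L)
  expect_equal(su1$hmrs$n_probes, 1L)
  expect_false(su1$hmrs$represented)
})

test_that("HMR means equal a direct per-HMR oracle on random data", {
  set.seed(30)
  np <- 400L; ns <- 8L
  probes <- data.frame(probe_id = sprintf("p%03d", 1:np), chrom = "chr1",
                       pos = sort(sample.int(1e6, np)))
  beta <- matrix(runif(np * ns), np, ns)
  beta[sample.int(np * ns, 200L)] <- NA
  bm <- beta_matrix(beta, probes,
                    data.frame(sample_id = paste0("s", 1:ns),
                               label = "x", group = "cancer"))
  st <- seq(0L, 9.5e5, length.out = 50L)
  hmrs <- interval_set("chr1", as.integer(st), as.integer(st + 15000))
  su <- hmr_beta_summary(hmrs, bm)
  for (i in seq_len(50)) {
    sel <- probes$pos >= hmrs$start[i] & probes$pos < hmrs$end[i]
    for (j in seq_len(ns)) {
      v <- beta[sel, j]
      expected <- if (all(is.na(v)) || !length(v)) NA_real_ else mean(v, na.rm = TRUE)
      expect_equal(unname(su$mean_beta[i, j]), expected)
    }
  }
})

test_that("array confirmation applies the probe and level rules", {
  mb <- rbind(rep(0.05, 4), rep(0.05, 4), c(0.05, 0.35, 0.05, 0.05))
  su <- mk_summary(mb, n_probes = c(8L, 3L, 8L), groups = rep("normal", 4))
  conf <- confirm_hypomethylated(su)
  expect_equal(conf, c(TRUE, FALSE, FALSE))  # probe-poor and 0.35 both fail
  # boundary: exactly 0.30 passes (rule is <= 30%), exactly 6 probes passes
  su2 <- mk_summary(matrix(0.30, 1, 4), n_probes = 6L,
                    groups = rep("normal", 4))
  expect_true(confirm_hypomethylated(su2))
})

test_that("event calling implements strict intensity and frequency rules", {
  mb <- rbind(c(0.40, 0.40, 0.40, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
              rep(0, 10),
              c(0.33, 0.33, 0.33, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  su <- mk_summary(mb, n_probes = rep(6L, 3), groups = rep("cancer", 10))
  ev <- call_hypermethylation_events(su)
  expect_equal(ev$is_event, c(TRUE, FALSE, FALSE))  # 0.33 is not > 0.33
  expect_equal(ev$event_frequency[1], 0.3)
})

test_that("event calls equal a brute-force double loop on a random matrix", {
  set.seed(31)
  mb <- matrix(runif(200 * 50), 200, 50)
  mb[sample.int(200 * 50, 400)] <- NA
  su <- mk_summary(mb, n_probes = rep(6L, 200), groups = rep("cancer", 50))
  ev <- call_hypermethylation_events(su, intensity = 0.6, frequency = 0.4)
  for (i in seq_len(200)) {
    hits <- 0L; nobs <- 0L
    for (j in seq_len(50)) {
      if (is.na(mb[i, j])) next
      nobs <- nobs + 1L
      if (mb[i, j] > 0.6) hits <- hits + 1L
    }
    expect_equal(ev$is_event[i], hits / nobs >= 0.4)
  }
})

test_that("event sets shrink as thresholds rise", {
  set.seed(32)
  mb <- matrix(runif(100 * 30), 100, 30)
  su <- mk_summary(mb, n_probes = rep(6L, 100), groups = rep("cancer", 30))
  for (freq in c(0.1, 0.3)) {
    n_ev <- vapply(seq(0.1, 0.9, by = 0.2), function(x)
      sum(call_hypermethylation_events(su, intensity = x,
                                       frequency = freq)$is_event), 0L)
    expect_true(all(diff(n_ev) <= 0))
  }
  for (int in c(0.3, 0.6)) {
    n_ev <- vapply(seq(0.05, 0.85, by = 0.2), function(x)
      sum(call_hypermethylation_events(su, intensity = int,
                                       frequency = x)$is_event), 0L)
    expect_true(all(diff(n_ev) <= 0))
  }
})

test_that("positive-selection candidates respect promoter, probe and frequency rules", {
  mb <- rbind(c(0.6, 0.6, rep(0.1, 98)),    # promoter, 2% at 0.6
              c(0.6, 0.6, rep(0.1, 98)),    # same but not a promoter
              c(0.6, 0.6, rep(0.1, 98)),    # promoter but 1 probe
              c(0.6, rep(0.1, 99)))         # 1% only: not > 1%
  su <- mk_summary(mb, n_probes = c(3L, 3L, 1L, 3L),
                   groups = rep("cancer", 100))
  cand <- positive_selection_candidates(su,
                                        promoter_flags = c(TRUE, FALSE, TRUE,
                                                           TRUE))
  expect_equal(cand$hmr, rownames(su$mean_beta)[1])
  expect_equal(cand$frequency, 0.02)
})

test_that("solid-only restricts the candidate denominator", {
  mb <- matrix(0.1, 1, 20)
  mb[1, 1] <- 0.9   # the only high-intensity sample is a leukemia
  labels <- c("leukemia", rep("lung", 19))
  su <- mk_summary(mb, n_probes = 2L, groups = rep("cancer", 20),
                   labels = labels)
  all_types <- positive_selection_candidates(su, promoter_flags = TRUE)
  expect_equal(nrow(all_types), 1L)
  solid <- positive_selection_candidates(su, promoter_flags = TRUE,
                                         solid_only = TRUE,
                                         solid_types = "lung")
  expect_equal(nrow(solid), 0L)
})

test_that("perfectly separated t-HMRs give AUC 1 and permutation gives ~0.5", {
  tissues <- rep(c("colon", "liver", "lung"), each = 4)
  hmr_tissue <- rep(c("colon", "liver", "lung"), times = 5)
  mb <- outer(hmr_tissue, tissues, function(h, s) ifelse(h == s, 0, 1))
  su <- mk_summary(mb, n_probes = rep(3L, 15), groups = rep("normal", 12),
                   labels = tissues)
  val <- validate_catalog(su, hmr_tissue)
  expect_equal(val$auc, 1.0)
  i50 <- which.min(abs(val$thresholds - 0.5))
  expect_equal(val$sensitivity[i50], 1.0)
  expect_equal(val$fpr[i50], 0.0)

  set.seed(35)
  mb2 <- matrix(runif(60 * 24), 60, 24)
  lab2 <- rep(c("a", "b", "c"), each = 8)
  ht2 <- rep(c("a", "b", "c"), times = 20)
  su2 <- mk_summary(mb2, n_probes = rep(3L, 60), groups = rep("normal", 24),
                    labels = lab2)
  aucs <- vapply(1:5, function(i)
    validate_catalog(su2, ht2, sample(lab2))$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("sweep counts equal a direct double loop", {
  set.seed(36)
  mb <- matrix(runif(20 * 9), 20, 9)
  lab <- rep(c("a", "b", "c"), each = 3)
  ht <- rep(c("a", "b"), length.out = 20)
  su <- mk_summary(mb, n_probes = rep(3L, 20), groups = rep("normal", 9),
                   labels = lab)
  grid <- c(0.25, 0.5, 0.75)
  val <- validate_catalog(su, ht, threshold_grid = grid)
  for (gi in seq_along(grid)) {
    tp <- fp <- nm <- nu <- 0L
    for (i in 1:20) for (j in 1:9) {
      if (ht[i] == lab[j]) {
        nm <- nm + 1L
        if (mb[i, j] < grid[gi]) tp <- tp + 1L
      } else {
        nu <- nu + 1L
        if (mb[i, j] < grid[gi]) fp <- fp + 1L
      }
    }
    expect_equal(val$sensitivity[gi], tp / nm)
    expect_equal(val$fpr[gi], fp / nu)
  }
})

test_that("validation requires matched pairs", {
  su <- mk_summary(matrix(0.5, 2, 3), n_probes = c(2L, 2L),
                   groups = rep("normal", 3), labels = rep("liver", 3))
  expect_error(validate_catalog(su, c("colon", "lung")), "no matched")
})

test_that("clustering recovers planted blocks and honors Jaccard geometry", {
  set.seed(37)
  mb <- matrix(0.05, 40, 12)
  mb[1:20, 1:6] <- 0.8    # block A events
  mb[21:40, 7:12] <- 0.8  # block B events
  mb <- mb + matrix(runif(40 * 12, 0, 0.02), 40, 12)
  su <- mk_summary(mb, n_probes = rep(3L, 40), groups = rep("cancer", 12))
  cl <- cluster_samples(su, k = 2L)
  expect_equal(length(unique(cl$labels[1:6])), 1L)
  expect_equal(length(unique(cl$labels[7:12])), 1L)
  expect_true(cl$labels[1] != cl$labels[7])

  # duplicated sample sits at distance zero from its twin
  mb2 <- cbind(mb, mb[, 1])
  colnames(mb2) <- c(colnames(su$mean_beta), "twin")
  su2 <- mk_summary(mb2, n_probes = rep(3L, 40), groups = rep("cancer", 13))
  d <- as.matrix(cluster_samples(su2)$distance)
  expect_equal(d[1, 13], 0)

  # Jaccard distances equal the set formula
  B <- su$mean_beta > 0.33
  d1 <- as.matrix(cluster_samples(su)$distance)
  for (i in c(1, 5)) for (j in c(7, 12)) {
    inter <- sum(B[, i] & B[, j]); uni <- sum(B[, i] | B[, j])
    expect_equal(d1[i, j], 1 - inter / uni)
  }
})

test_that("all-identical samples are flagged as a single trivial cluster", {
  su <- mk_summary(matrix(0.05, 5, 4), n_probes = rep(2L, 5),
                   groups = rep("cancer", 4))
  expect_warning(cluster_samples(su), "single cluster")
})
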