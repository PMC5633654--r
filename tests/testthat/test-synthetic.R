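test_that("generators are seed-deterministic", {
  d1 <- genome_design(n_chromosomes = 1L, chromosome_bp = 3e5, seed = 50,
                      n_c = 3L, n_frequent = 2L, n_t_per_tissue = 1L,
                      n_null = 1L)
  d2 <- genome_design(n_chromosomes = 1L, chromosome_bp = 3e5, seed = 50,
                      n_c = 3L, n_frequent = 2L, n_t_per_tissue = 1L,
                      n_null = 1L)
  expect_identical(d1$cpg, d2$cpg)
  expect_identical(d1$islands, d2$islands)

  m1 <- simulate_methylome(d1, "tissue1", 10, seed = 51)
  m2 <- simulate_methylome(d1, "tissue1", 10, seed = 51)
  expect_identical(as.data.frame(m1), as.data.frame(m2))

  a1 <- simulate_alteration_matrix(5, 20, 0.1, seed = 52)
  a2 <- simulate_alteration_matrix(5, 20, 0.1, seed = 52)
  expect_identical(a1, a2)
})

test_that("planted catalog architecture obeys the partition algebra", {
  d <- genome_design(seed = 53, n_chromosomes = 1L, chromosome_bp = 2e6,
                     n_c = 6L, n_frequent = 3L, n_t_per_tissue = 2L,
                     n_null = 2L)
  for (t in d$tissues) {
    others <- do.call(rbind, lapply(setdiff(d$tissues, t), function(o)
      as.data.frame(d$planted[[o]])))
    expect_equal(total_bp(intersect_intervals(d$planted_kind$t_hmrs[[t]],
                                              interval_set(others))), 0)
    # c-HMRs are carried by every tissue
    expect_equal(total_bp(intersect_intervals(d$planted_kind$c_hmrs,
                                              d$planted[[t]])),
                 total_bp(d$planted_kind$c_hmrs))
  }
})

test_that("a methylome without planted HMRs sits at 70-80% methylation", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 1e6, n_c = 0L,
                     n_frequent = 2L, n_t_per_tissue = 0L, n_null = 0L,
                     n_tissues = 4L, frequent_tissues = 3L, seed = 54)
  # tissue4 is outside the frequent subset: nothing planted for it
  expect_equal(nrow(d$planted$tissue4), 0L)
  m <- simulate_methylome(d, "tissue4", coverage_mean = 15, seed = 55)
  expect_gt(mean(m$level), 0.70)
  expect_lt(mean(m$level), 0.80)
})

test_that("per-CpG levels match the design Beta moments", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 1e6, n_c = 0L,
                     n_frequent = 2L, n_t_per_tissue = 0L, n_null = 0L,
                     n_tissues = 4L, frequent_tissues = 3L, seed = 56)
  m <- simulate_methylome(d, "tissue4", coverage_mean = 20, seed = 57)
  truth <- attr(m, "true_level")
  n <- length(truth)
  expect_lt(abs(mean(truth) - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  beta_var <- 7.5 * 2.5 / ((10)^2 * 11)
  expect_lt(abs(var(truth) - beta_var), 0.2 * beta_var)
})

test_that("coverage below one read is rejected", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 2e5, seed = 58,
                     n_c = 2L, n_frequent = 2L, n_t_per_tissue = 1L,
                     n_null = 1L)
  expect_error(simulate_methylome(d, "tissue1", coverage_mean = 0.5),
               "coverage_mean")
})

test_that("the cancer series loses methylation monotonically", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 2e6, seed = 59,
                     n_c = 5L, n_frequent = 2L, n_t_per_tissue = 2L,
                     n_null = 2L)
  ser <- simulate_cancer_series(d, coverage_mean = 12, seed = 60)
  gm <- ser$truth$global_mean
  expect_true(gm["normal"] > gm["primary"])
  expect_true(gm["primary"] > gm["metastasis"])
  expect_gt(total_bp(ser$truth$pmd_metastasis),
            total_bp(ser$truth$pmd_primary))
})

test_that("planted hyper events are recovered by the DMR caller", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 2e6, seed = 61,
                     n_c = 8L, n_frequent = 2L, n_t_per_tissue = 2L,
                     n_null = 2L)
  ser <- simulate_cancer_series(d, coverage_mean = 15, seed = 62)
  pa <- smooth_profile(ser$normal)
  pb <- smooth_profile(ser$primary)
  dm <- call_dmrs(pb, pa)
  hyper <- interval_set(as.data.frame(dm[dm$direction == "hyper", ]))
  hit <- overlap_any(ser$truth$hyper_hmrs, hyper)
  expect_gte(mean(hit), 0.9)
})

test_that("beta cohorts plant exact event frequencies and clean baselines", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 2e6, seed = 63,
                     n_c = 10L, n_frequent = 2L, n_t_per_tissue = 1L,
                     n_null = 2L, n_tissues = 4L, frequent_tissues = 3L)
  sim <- simulate_beta_cohort(d, cancer_types = paste0("c", 1:4),
                              n_per_type = 20L, events_per_type = 3L,
                              noise_sd = 0, seed = 64)
  # noiseless, eventless HMRs: every c-island mean is <= 0.15 in normals
  isl <- sim$truth$islands
  cis <- interval_set(isl[isl$kind == "c", c("chrom", "start", "end")])
  su <- hmr_beta_summary(cis, sim$betas, min_probes = 2L)
  normals <- su$mean_beta[, sim$betas$samples$group == "normal", drop = FALSE]
  expect_lte(max(normals), 0.15)
  # planted per-type frequency is exact
  ind <- sim$truth$event_indicator
  for (ct in paste0("c", 1:4)) {
    cols <- grepl(paste0("^", ct, "_"), colnames(ind))
    loci <- as.character(sim$truth$event_loci[[ct]])
    counts <- rowSums(ind[loci, cols, drop = FALSE])
    expect_true(all(counts == round(0.3 * 20)))
  }
})

test_that("noiseless eventless cohorts confirm every common HMR", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 1e6, seed = 65,
                     n_c = 6L, n_frequent = 2L, n_t_per_tissue = 1L,
                     n_null = 1L, n_tissues = 4L, frequent_tissues = 3L)
  sim <- simulate_beta_cohort(d, cancer_types = "c1", n_per_type = 5L,
                              events_per_type = 0L, noise_sd = 0,
                              probes_per_hmr = c(6L, 8L), seed = 66)
  isl <- sim$truth$islands
  cis <- interval_set(isl[isl$kind == "c", c("chrom", "start", "end")])
  su <- hmr_beta_summary(cis, sim$betas, min_probes = 6L)
  expect_true(all(confirm_hypomethylated(su)))
  ev <- call_hypermethylation_events(su)
  expect_false(any(ev$is_event))
})

test_that("alteration matrices honor rates and exclusivity", {
  m <- simulate_alteration_matrix(50, 200, per_gene_rates = 0.1, seed = 67)
  # column sums ~ Binomial(50, 0.1)
  expect_lt(abs(mean(colSums(m)) - 5), 0.5)

  excl <- list(s = 1:4)
  me <- simulate_alteration_matrix(10, 60, per_gene_rates = 0.15,
                                   exclusive_sets = excl, seed = 68)
  co <- crossprod(t(me[1:4, ]))
  expect_true(all(co[upper.tri(co)] == 0))

  expect_error(simulate_alteration_matrix(4, 6, per_gene_rates = 0.9,
                                          exclusive_sets = list(s = 1:4),
                                          seed = 69),
               "exceeds samples")
})

test_that("generated data satisfy downstream preconditions end to end", {
  d <- genome_design(n_chromosomes = 1L, chromosome_bp = 8e5, seed = 70,
                     n_c = 4L, n_frequent = 2L, n_t_per_tissue = 1L,
                     n_null = 1L, n_tissues = 3L, frequent_tissues = 2L)
  hmrs <- lapply(d$tissues, function(t)
    segment_hmrs(simulate_methylome(d, t, 12, seed = 71), seed = 72))
  names(hmrs) <- d$tissues
  expect_s3_class(build_catalog(hmrs), "hmr_catalog")
})
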