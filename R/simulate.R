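#' Design a synthetic genome with planted HMR architecture
#'
#' Lays out CpG positions as a clustered point process — dense CpG islands
#' (10 bp mean spacing, 50-200 CpGs) at planted regulatory sites over a
#' sparse background — and plants an HMR architecture across tissues that
#' obeys the catalog algebra by construction: common HMRs hypomethylated in
#' every tissue, frequent HMRs hypomethylated in a fixed majority subset,
#' tissue-specific HMRs unique to one tissue, plus islands that stay
#' methylated everywhere. Each island carries a gene with its promoter on
#' the island span.
#'
#' @param n_chromosomes,chromosome_bp genome shape (default 2 x 5 Mb).
#' @param n_tissues number of tissues (default 8).
#' @param n_c,n_frequent,n_t_per_tissue,n_null planted island counts:
#'   common, frequent, tissue-specific per tissue, and always-methylated.
#' @param frequent_tissues how many tissues carry each frequent HMR
#'   (default 5 of 8, i.e. >50%).
#' @param bg_spacing_bp mean background CpG spacing (default 300, giving
#'   roughly 50k CpGs at the default genome size).
#' @param island_spacing_bp mean island CpG spacing (default 10).
#' @param island_cpgs range of CpGs per island (default 50-200).
#' @param seed integer seed.
#' @return An object of class `genome_design`: `chroms`, `cpg`
#'   (chrom/pos), `islands`, `promoters`, `planted` (tissue -> interval
#'   set), `planted_kind` (c/frequent/t truth sets) and `params`.
#' @export
genome_design <- function(n_chromosomes = 2L, chromosome_bp = 5e6,
                          n_tissues = 8L, n_c = 30L, n_frequent = 8L,
                          n_t_per_tissue = 12L, n_null = 20L,
                          frequent_tissues = 5L, bg_spacing_bp = 300,
                          island_spacing_bp = 10, island_cpgs = c(50L, 200L),
                          seed = 1L) {
  stopifnot(n_tissues >= 2L, frequent_tissues > n_tissues / 2,
            frequent_tissues < n_tissues)
  set.seed(seed)
  tissues <- paste0("tissue", seq_len(n_tissues))
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chromosomes)),
                       length = as.integer(chromosome_bp))
  n_islands <- n_c + n_frequent + n_t_per_tissue * n_tissues + n_null
  kinds <- c(rep("c", n_c), rep("frequent", n_frequent),
             rep("t", n_t_per_tissue * n_tissues), rep("null", n_null))
  t_owner <- c(rep(NA_character_, n_c + n_frequent),
               rep(tissues, each = n_t_per_tissue), rep(NA_character_, n_null))
  # shuffle island placement so kinds are interleaved along the genome
  ord <- sample.int(n_islands)
  kinds <- kinds[ord]; t_owner <- t_owner[ord]
  # island anchors: evenly spread slots with jitter, min ~20 kb apart
  per_chrom <- ceiling(n_islands / n_chromosomes)
  anchors <- list()
  for (ci in seq_len(n_chromosomes)) {
    take <- min(per_chrom, n_islands - (ci - 1L) * per_chrom)
    if (take <= 0) break
    slot <- chromosome_bp / (per_chrom + 1)
    centers <- round(slot * seq_len(take) + stats::runif(take, -0.2, 0.2) * slot)
    anchors[[ci]] <- data.frame(chrom = chroms$chrom[ci], center = centers)
  }
  anchors <- do.call(rbind, anchors)[seq_len(n_islands), ]

  cpg <- list(); islands <- list()
  for (i in seq_len(n_islands)) {
    n_cpg <- sample(island_cpgs[1]:island_cpgs[2], 1L)
    gaps <- 2L + stats::rgeom(n_cpg - 1L, 1 / (island_spacing_bp - 2))
    pos <- anchors$center[i] + cumsum(c(0L, gaps))
    cpg[[i]] <- data.frame(chrom = anchors$chrom[i], pos = as.integer(pos))
    islands[[i]] <- data.frame(island_id = i, chrom = anchors$chrom[i],
                               start = as.integer(pos[1L]),
                               end = as.integer(pos[n_cpg] + 2L),
                               kind = kinds[i], tissue = t_owner[i],
                               gene = sprintf("gene%03d", i),
                               stringsAsFactors = FALSE)
  }
  islands <- do.call(rbind, islands)
  # background CpGs
  for (ci in seq_len(n_chromosomes)) {
    gaps <- 2L + stats::rgeom(ceiling(chromosome_bp / bg_spacing_bp * 1.2),
                              1 / (bg_spacing_bp - 2))
    pos <- cumsum(as.numeric(gaps))
    pos <- pos[pos < chromosome_bp - 2]
    cpg[[length(cpg) + 1L]] <- data.frame(chrom = chroms$chrom[ci],
                                          pos = as.integer(pos))
  }
  cpg <- do.call(rbind, cpg)
  cpg <- cpg[!duplicated(paste(cpg$chrom, cpg$pos)), ]
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  rownames(cpg) <- NULL

  freq_subset <- tissues[seq_len(frequent_tissues)]
  planted <- lapply(tissues, function(t) {
    own <- islands$kind == "c" |
      (islands$kind == "frequent" & t %in% freq_subset) |
      (islands$kind == "t" & !is.na(islands$tissue) & islands$tissue == t)
    interval_set(islands[own, c("chrom", "start", "end")])
  })
  names(planted) <- tissues
  planted_kind <- list(
    c_hmrs = interval_set(islands[islands$kind == "c", c("chrom", "start", "end")]),
    frequent_hmrs = interval_set(islands[islands$kind == "frequent",
                                         c("chrom", "start", "end")]),
    t_hmrs = lapply(stats::setNames(tissues, tissues), function(t)
      interval_set(islands[islands$kind == "t" & !is.na(islands$tissue) &
                             islands$tissue == t, c("chrom", "start", "end")])))
  promoters <- data.frame(gene = islands$gene, chrom = islands$chrom,
                          start = islands$start, end = islands$end,
                          stringsAsFactors = FALSE)
  structure(list(chroms = chroms, cpg = cpg, islands = islands,
                 promoters = promoters, planted = planted,
                 planted_kind = planted_kind, tissues = tissues,
                 frequent_subset = freq_subset,
                 params = list(n_chromosomes = n_chromosomes,
                               chromosome_bp = chromosome_bp,
                               bg_spacing_bp = bg_spacing_bp, seed = seed)),
            class = "genome_design")
}

#' @export
print.genome_design <- function(x, ...) {
  cat(sprintf("<genome_design> %d chromosome(s) x %g bp, %d CpGs, %d islands, %d tissues\n",
              nrow(x$chroms), x$chroms$length[1], nrow(x$cpg),
              nrow(x$islands), length(x$tissues)))
  invisible(x)
}

# truncated Poisson (>= 1) via inverse CDF
.rpois_pos <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# per-CpG true levels for one tissue: background Beta vs planted-HMR Beta
.true_levels <- function(design, tissue, bg_shape = c(7.5, 2.5),
                         hmr_shape = c(1, 19)) {
  n <- nrow(design$cpg)
  lv <- stats::rbeta(n, bg_shape[1], bg_shape[2])
  pts <- interval_set(design$cpg$chrom, design$cpg$pos, design$cpg$pos + 1L)
  inside <- overlap_any(pts, design$planted[[tissue]])
  # interval_set() keeps (chrom,pos) sort order, matching design$cpg
  lv[inside] <- stats::rbeta(sum(inside), hmr_shape[1], hmr_shape[2])
  lv
}

#' Simulate a WGBS methylome with planted HMRs
#'
#' Per-CpG true levels are drawn from Beta(7.5, 2.5) (mean 0.75, matching
#' the 70-80% global methylation of normal somatic methylomes) outside
#' planted regions and Beta(1, 19) (mean 0.05) inside the tissue's planted
#' HMRs; read depths are truncated-Poisson(coverage_mean) >= 1 and
#' methylated counts Binomial(depth, level).
#'
#' @param design a [genome_design()].
#' @param tissue tissue whose planted HMR set is hypomethylated.
#' @param coverage_mean mean read depth (default 15; must be >= 1).
#' @param seed integer seed.
#' @param bg_shape,hmr_shape Beta shape pairs for background / HMR levels.
#' @param status sample status label.
#' @return A [methylome()]; the planted truth intervals are attached as
#'   attribute `"planted"` and per-CpG true levels as `"true_level"`.
#' @export
simulate_methylome <- function(design, tissue, coverage_mean = 15, seed = 1L,
                               bg_shape = c(7.5, 2.5), hmr_shape = c(1, 19),
                               status = "normal") {
  if (coverage_mean < 1) stop("simulate_methylome: coverage_mean must be >= 1")
  stopifnot(tissue %in% design$tissues)
  set.seed(seed)
  lv <- .true_levels(design, tissue, bg_shape, hmr_shape)
  n <- nrow(design$cpg)
  depth <- .rpois_pos(n, coverage_mean)
  meth <- stats::rbinom(n, depth, lv)
  m <- methylome(data.frame(chrom = design$cpg$chrom, pos = design$cpg$pos,
                            meth = meth, total = depth),
                 sample_id = paste0(tissue, "_wgbs"), tissue = tissue,
                 status = status)
  attr(m, "planted") <- design$planted[[tissue]]
  attr(m, "true_level") <- lv
  m
}

#' Parameters of a synthetic cancer methylome
#'
#' @param n_pmd_primary,n_pmd_extra_metastasis number of partially
#'   methylated domains (PMDs) planted in the primary and added in the
#'   metastasis.
#' @param pmd_bp PMD block size in bp.
#' @param pmd_level_range intermediate methylation range of PMDs.
#' @param n_hyper_events planted focal hypermethylation events (on the
#'   tissue's planted HMRs).
#' @param hyper_intensity target mean level of hypermethylated HMRs in the
#'   primary; the metastasis gains `hyper_gain` on top.
#' @param hyper_gain extra intensity in the metastasis.
#' @param shift_primary,shift_metastasis global background methylation loss.
#' @return An object of class `cancer_design`.
#' @export
cancer_design <- function(n_pmd_primary = 6L, n_pmd_extra_metastasis = 6L,
                          pmd_bp = 2e5, pmd_level_range = c(0.35, 0.65),
                          n_hyper_events = 10L, hyper_intensity = 0.6,
                          hyper_gain = 0.15, shift_primary = 0.05,
                          shift_metastasis = 0.10) {
  stopifnot(pmd_level_range[1] > 0.3, pmd_level_range[2] < 0.7,
            shift_metastasis >= shift_primary)
  structure(as.list(environment()), class = "cancer_design")
}

#' Simulate a matched normal / primary / metastasis methylome series
#'
#' The primary tumor inherits the normal architecture plus planted PMD
#' blocks, focal promoter hypermethylation events and a global background
#' methylation loss; the metastasis inherits every primary alteration and
#' adds further PMD coverage, hypermethylation intensity and global loss,
#' so planted global means are strictly decreasing
#' normal > primary > metastasis.
#'
#' @param design a [genome_design()].
#' @param cancer a [cancer_design()].
#' @param tissue tissue of origin.
#' @param coverage_mean mean read depth.
#' @param seed integer seed.
#' @return List with methylomes `normal`, `primary`, `metastasis` and a
#'   `truth` list (PMD intervals, hypermethylated HMR intervals per stage,
#'   planted global mean per stage).
#' @export
simulate_cancer_series <- function(design, cancer = cancer_design(),
                                   tissue = design$tissues[1],
                                   coverage_mean = 15, seed = 1L) {
  set.seed(seed)
  normal <- simulate_methylome(design, tissue, coverage_mean,
                               seed = seed + 1L, status = "normal")
  planted <- design$planted[[tissue]]
  n_pmd_total <- cancer$n_pmd_primary + cancer$n_pmd_extra_metastasis
  pmds <- list()
  for (i in seq_len(n_pmd_total)) {
    ci <- sample.int(nrow(design$chroms), 1L)
    s <- floor(stats::runif(1, 0, design$chroms$length[ci] - cancer$pmd_bp))
    pmds[[i]] <- data.frame(chrom = design$chroms$chrom[ci],
                            start = as.integer(s),
                            end = as.integer(s + cancer$pmd_bp))
  }
  pmds <- interval_set(do.call(rbind, pmds))
  pmd_primary <- pmds[seq_len(min(cancer$n_pmd_primary, nrow(pmds))), ]
  hyper_pool <- planted[sample.int(nrow(planted),
                                   min(cancer$n_hyper_events, nrow(planted))), ]
  hyper_pool <- interval_set(hyper_pool)

  make_stage <- function(shift, pmd_set, hyper_intensity, stage_seed, status, id) {
    set.seed(stage_seed)
    prec <- 10
    bg_mean <- 0.75 - shift
    lv <- .true_levels(design, tissue,
                       bg_shape = c(bg_mean * prec, (1 - bg_mean) * prec))
    pts <- interval_set(design$cpg$chrom, design$cpg$pos, design$cpg$pos + 1L)
    in_pmd <- overlap_any(pts, interval_set(pmd_set))
    lv[in_pmd] <- stats::runif(sum(in_pmd), cancer$pmd_level_range[1],
                               cancer$pmd_level_range[2])
    in_hyper <- overlap_any(pts, hyper_pool)
    hp <- min(hyper_intensity, 0.95)
    lv[in_hyper] <- stats::rbeta(sum(in_hyper), hp * prec, (1 - hp) * prec)
    depth <- .rpois_pos(length(lv), coverage_mean)
    meth <- stats::rbinom(length(lv), depth, lv)
    m <- methylome(data.frame(chrom = design$cpg$chrom, pos = design$cpg$pos,
                              meth = meth, total = depth),
                   sample_id = id, tissue = tissue, status = status)
    attr(m, "true_level") <- lv
    m
  }
  primary <- make_stage(cancer$shift_primary, pmd_primary,
                        cancer$hyper_intensity, seed + 2L, "cancer_primary",
                        paste0(tissue, "_primary"))
  metastasis <- make_stage(cancer$shift_metastasis, pmds,
                           cancer$hyper_intensity + cancer$hyper_gain,
                           seed + 3L, "metastasis",
                           paste0(tissue, "_metastasis"))
  truth <- list(
    pmd_primary = pmd_primary, pmd_metastasis = pmds,
    hyper_hmrs = hyper_pool,
    global_mean = c(normal = mean(attr(normal, "true_level")),
                    primary = mean(attr(primary, "true_level")),
                    metastasis = mean(attr(metastasis, "true_level"))))
  list(normal = normal, primary = primary, metastasis = metastasis,
       truth = truth)
}

#' Simulate an array-style beta-value cohort with planted events
#'
#' Places `probes_per_hmr` probes in every planted island, then draws
#' per-sample per-HMR true betas from the planted state — hypomethylated
#' (~Uniform(0.05, 0.15)) where the sample's tissue carries the HMR,
#' methylated (~Uniform(0.65, 0.85)) otherwise — and, for cancer samples,
#' plants hypermethylation events: per cancer type, `events_per_type`
#' common HMRs are event loci, each carried by exactly
#' `round(event_frequency * n_per_type)` randomly chosen cancer samples of
#' that type at intensity Uniform(`event_intensity`), so the planted
#' frequency is a design condition rather than a Bernoulli realization.
#' Probe betas are the HMR truth plus Gaussian noise, clamped to \[0, 1\].
#'
#' @param design a [genome_design()].
#' @param cancer_types character vector of cancer type names; each maps to
#'   a tissue of origin (recycled over `design$tissues`).
#' @param n_per_type cancer samples per type (default 25).
#' @param events_per_type planted event HMRs per type (default 5).
#' @param n_normal_per_tissue normal samples per tissue (default 2).
#' @param probes_per_hmr integer range of probes per island (default 2-8).
#' @param noise_sd probe-level Gaussian noise s.d. (default 0.05).
#' @param event_frequency planted per-sample event probability
#'   (default 0.3).
#' @param event_intensity range of event beta intensities
#'   (default c(0.5, 0.9)).
#' @param seed integer seed.
#' @return List with `betas` (a [beta_matrix()]) and `truth` (event loci
#'   per type, per-sample event indicators, planted frequencies, island
#'   table).
#' @export
simulate_beta_cohort <- function(design, cancer_types = paste0("cancer", 1:12),
                                 n_per_type = 25L, events_per_type = 5L,
                                 n_normal_per_tissue = 2L,
                                 probes_per_hmr = c(2L, 8L), noise_sd = 0.05,
                                 event_frequency = 0.3,
                                 event_intensity = c(0.5, 0.9), seed = 1L) {
  set.seed(seed)
  islands <- design$islands
  type_tissue <- stats::setNames(
    rep(design$tissues, length.out = length(cancer_types)), cancer_types)
  # probes
  probes <- list()
  for (i in seq_len(nrow(islands))) {
    np <- sample(probes_per_hmr[1]:probes_per_hmr[2], 1L)
    span <- islands$end[i] - islands$start[i]
    off <- sort(sample.int(span, min(np, span)) - 1L)
    probes[[i]] <- data.frame(
      probe_id = sprintf("cg%05d_%02d", i, seq_along(off)),
      chrom = islands$chrom[i], pos = islands$start[i] + off,
      island_id = islands$island_id[i], stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probes)

  samples <- list(); truth_events <- list()
  # normals
  for (t in design$tissues) for (r in seq_len(n_normal_per_tissue))
    samples[[length(samples) + 1L]] <- list(
      sample_id = sprintf("%s_N%02d", t, r), label = t, group = "normal",
      tissue = t, type = NA_character_)
  # cancers
  event_loci <- list()
  c_ids <- islands$island_id[islands$kind == "c"]
  for (ct in cancer_types) {
    event_loci[[ct]] <- sort(sample(c_ids, min(events_per_type, length(c_ids))))
    for (r in seq_len(n_per_type))
      samples[[length(samples) + 1L]] <- list(
        sample_id = sprintf("%s_T%02d", ct, r), label = ct, group = "cancer",
        tissue = type_tissue[[ct]], type = ct)
  }
  sample_df <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, label = s$label, group = s$group,
               stringsAsFactors = FALSE)))

  hypo_state <- function(tissue) {
    # which islands are hypomethylated for this tissue (planted state)
    islands$kind == "c" |
      (islands$kind == "frequent" & tissue %in% design$frequent_subset) |
      (islands$kind == "t" & !is.na(islands$tissue) & islands$tissue == tissue)
  }
  beta <- matrix(NA_real_, nrow(probes), length(samples))
  event_ind <- matrix(FALSE, nrow(islands), length(samples),
                      dimnames = list(islands$island_id,
                                      vapply(samples, `[[`, "", "sample_id")))
  types <- vapply(samples, function(s)
    if (is.na(s$type)) "" else s$type, character(1))
  n_carriers <- round(event_frequency * n_per_type)
  for (ct in cancer_types) {
    type_idx <- which(types == ct)
    for (locus in event_loci[[ct]]) {
      carriers <- sample(type_idx, min(n_carriers, length(type_idx)))
      event_ind[match(locus, islands$island_id), carriers] <- TRUE
    }
  }
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    hypo <- hypo_state(s$tissue)
    truth_b <- ifelse(hypo, stats::runif(nrow(islands), 0.05, 0.15),
                      stats::runif(nrow(islands), 0.65, 0.85))
    has_ev <- which(event_ind[, si])
    if (length(has_ev))
      truth_b[has_ev] <-
        stats::runif(length(has_ev), event_intensity[1], event_intensity[2])
    b <- truth_b[match(probes$island_id, islands$island_id)]
    if (noise_sd > 0) b <- b + stats::rnorm(length(b), 0, noise_sd)
    beta[, si] <- pmin(pmax(b, 0), 1)
  }
  bm <- beta_matrix(beta, probes[, c("probe_id", "chrom", "pos")], sample_df)
  list(betas = bm,
       truth = list(event_loci = event_loci, event_indicator = event_ind,
                    event_frequency = event_frequency,
                    planted_frequency = n_carriers / n_per_type,
                    islands = islands, probes = probes,
                    type_tissue = type_tissue))
}

#' Simulate a binary alteration matrix
#'
#' Null mode: gene-sample alterations are independent Bernoulli with
#' probability `rate * multiplier` (clamped to \[0, 1\]), giving
#' heterogeneous per-sample burdens. Exclusive mode: within each planted
#' set, each gene's altered samples are drawn disjointly from the
#' remaining samples, so no within-set sample is altered twice.
#'
#' @param n_genes,n_samples matrix shape.
#' @param per_gene_rates alteration rate per gene (recycled).
#' @param burden_multipliers per-sample burden multiplier (recycled).
#' @param exclusive_sets optional list of gene-index (or gene-name)
#'   vectors made mutually exclusive.
#' @param seed integer seed.
#' @return Binary genes x samples matrix; planted exclusive sets in
#'   attribute `"exclusive_sets"`.
#' @export
simulate_alteration_matrix <- function(n_genes, n_samples,
                                       per_gene_rates = 0.1,
                                       burden_multipliers = 1,
                                       exclusive_sets = NULL, seed = 1L) {
  set.seed(seed)
  rates <- rep_len(per_gene_rates, n_genes)
  mult <- rep_len(burden_multipliers, n_samples)
  stopifnot(all(rates >= 0), all(mult >= 0))
  genes <- sprintf("gene%03d", seq_len(n_genes))
  p <- pmin(outer(rates, mult), 1)
  calls <- matrix(stats::rbinom(n_genes * n_samples, 1L, p), n_genes, n_samples,
                  dimnames = list(genes, sprintf("s%03d", seq_len(n_samples))))
  if (!is.null(exclusive_sets)) {
    for (set in exclusive_sets) {
      gi <- if (is.character(set)) match(set, genes) else set
      stopifnot(!anyNA(gi))
      pool <- seq_len(n_samples)
      for (g in gi) {
        kg <- stats::rbinom(1L, n_samples, rates[g])
        if (kg > length(pool))
          stop("simulate_alteration_matrix: exclusive set demand exceeds samples")
        pick <- if (kg > 0L) sample(pool, kg, prob = mult[pool]) else integer(0)
        calls[g, ] <- 0L
        calls[g, pick] <- 1L
        pool <- setdiff(pool, pick)
      }
    }
  }
  attr(calls, "exclusive_sets") <- exclusive_sets
  calls
}
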