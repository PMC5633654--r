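#' Pipeline run configuration
#'
#' Collects every stage parameter with its documented default into a
#' validated, YAML-round-trippable configuration list. All randomness in a
#' run flows from the single `seed` via fixed per-stage offsets.
#'
#' @param seed root integer seed.
#' @param out_dir output directory.
#' @param stages subset of `c("segment", "catalog", "dmr", "cohort",
#'   "mutex")` to execute.
#' @param design list of [genome_design()] arguments overriding its
#'   defaults.
#' @param coverage_mean WGBS mean read depth.
#' @param min_cpgs,max_intra_gap_bp HMR segmentation parameters.
#' @param merge_gap_bp,frequent_fraction catalog parameters.
#' @param min_window_bp,smooth_min_cpgs smoothing parameters.
#' @param min_consecutive DMR run-length threshold.
#' @param cohort list of [simulate_beta_cohort()] arguments overriding its
#'   defaults.
#' @param intensity,frequency hypermethylation event thresholds.
#' @param confirm_max_beta,confirm_min_probes array confirmation rule.
#' @param dichotomize_at clustering dichotomization cutoff.
#' @param mutex_n_sims,mutex_epsilon mutual-exclusivity test parameters.
#' @param log_level `"quiet"` or `"verbose"`.
#' @return An object of class `methmap_config`.
#' @export
methmap_config <- function(seed = 1L, out_dir = tempfile("methmap_run_"),
                           stages = c("segment", "catalog", "dmr", "cohort",
                                      "mutex"),
                           design = list(), coverage_mean = 15,
                           min_cpgs = 10L, max_intra_gap_bp = 5000L,
                           merge_gap_bp = 100L, frequent_fraction = 0.5,
                           min_window_bp = 1000L, smooth_min_cpgs = 20L,
                           min_consecutive = 6L, cohort = list(),
                           intensity = 0.33, frequency = 0.25,
                           confirm_max_beta = 0.30, confirm_min_probes = 6L,
                           dichotomize_at = 0.33, mutex_n_sims = 10000L,
                           mutex_epsilon = 0.01, log_level = "quiet") {
  cfg <- as.list(environment())
  class(cfg) <- "methmap_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented domain and fails naming
#' the offending field.
#'
#' @param config a `methmap_config` (or plain list with the same fields).
#' @return Invisibly `TRUE`; otherwise an error naming the field.
#' @export
validate_config <- function(config) {
  chk <- function(field, ok) {
    if (!isTRUE(ok)) stop("invalid config field: ", field, call. = FALSE)
  }
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  posint <- function(x) is.numeric(x) && length(x) == 1 && x >= 1
  chk("seed", is.numeric(config$seed) && length(config$seed) == 1)
  chk("stages", all(config$stages %in%
                      c("segment", "catalog", "dmr", "cohort", "mutex")))
  chk("coverage_mean", is.numeric(config$coverage_mean) && config$coverage_mean >= 1)
  chk("min_cpgs", posint(config$min_cpgs))
  chk("max_intra_gap_bp", posint(config$max_intra_gap_bp))
  chk("merge_gap_bp", is.numeric(config$merge_gap_bp) && config$merge_gap_bp >= 0)
  chk("frequent_fraction", in01(config$frequent_fraction))
  chk("min_window_bp", is.numeric(config$min_window_bp) && config$min_window_bp >= 0)
  chk("smooth_min_cpgs", posint(config$smooth_min_cpgs))
  chk("min_consecutive", posint(config$min_consecutive))
  chk("intensity", in01(config$intensity))
  chk("frequency", in01(config$frequency))
  chk("confirm_max_beta", in01(config$confirm_max_beta))
  chk("confirm_min_probes", posint(config$confirm_min_probes))
  chk("dichotomize_at", in01(config$dichotomize_at))
  chk("mutex_n_sims", posint(config$mutex_n_sims))
  chk("mutex_epsilon", is.numeric(config$mutex_epsilon) && config$mutex_epsilon > 0)
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a validated `methmap_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(methmap_config, raw)
  cfg
}

#' @param config a `methmap_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic genome design from the configured seed and
#' executes the configured stages: per-tissue HMR segmentation
#' (`segment`), the common/frequent/tissue-specific catalog (`catalog`),
#' smoothed-profile DMR calling on a matched normal/primary pair (`dmr`),
#' the array-scale cohort analysis (`cohort`) and the mutual-exclusivity
#' test on a planted alteration matrix (`mutex`). Every output table is
#' written under `config$out_dir` and recorded, with its MD5 checksum and
#' the full parameter set, in `manifest.json`. Identical configuration and
#' seed reproduce byte-identical outputs.
#'
#' @param config a [methmap_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (identical(config$log_level, "verbose")) message(...)
  manifest <- list(package = "methmap",
                   version = as.character(utils::packageVersion("methmap")),
                   seed = config$seed, stages = config$stages,
                   parameters = lapply(
                     unclass(config)[setdiff(names(unclass(config)),
                                             c("out_dir"))], identity),
                   outputs = list())
  add_output <- function(stage, name, path) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<-
      list(stage = stage, name = name, file = basename(path),
           md5 = unname(tools::md5sum(path)))
  }
  stage <- "design"
  result <- tryCatch({
    design <- do.call(genome_design,
                      c(config$design, list(seed = config$seed)))
    need_segment <- any(c("segment", "catalog") %in% config$stages)
    hmr_sets <- NULL
    if (need_segment) {
      stage <- "segment"
      say("segmenting ", length(design$tissues), " tissues")
      hmr_sets <- lapply(seq_along(design$tissues), function(i) {
        t <- design$tissues[i]
        m <- simulate_methylome(design, t, config$coverage_mean,
                                seed = config$seed + 100L + i)
        segment_hmrs(m, min_cpgs = config$min_cpgs,
                     max_intra_gap_bp = config$max_intra_gap_bp,
                     seed = config$seed + 200L + i)
      })
      names(hmr_sets) <- design$tissues
      if ("segment" %in% config$stages) {
        for (t in design$tissues) {
          p <- file.path(config$out_dir, paste0("hmrs_", t, ".bed"))
          write_bed(interval_set(as.data.frame(hmr_sets[[t]])), p)
          add_output("segment", paste0("hmrs_", t), p)
        }
        summ <- do.call(rbind, lapply(design$tissues, function(t) {
          s <- summarize_segmentation(hmr_sets[[t]],
                                      sum(as.numeric(design$chroms$length)))
          data.frame(tissue = t, n_hmrs = s$n_hmrs, coverage_bp = s$coverage_bp,
                     coverage_pct = s$coverage_pct,
                     mean_size_geometric = s$mean_size_geometric)
        }))
        p <- file.path(config$out_dir, "segmentation_summary.tsv")
        utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
        add_output("segment", "segmentation_summary", p)
      }
    }
    if ("catalog" %in% config$stages) {
      stage <- "catalog"
      catalog <- build_catalog(hmr_sets, merge_gap_bp = config$merge_gap_bp,
                               frequent_fraction = config$frequent_fraction)
      p <- file.path(config$out_dir, "c_hmrs.bed")
      write_bed(catalog$c_hmrs, p); add_output("catalog", "c_hmrs", p)
      p <- file.path(config$out_dir, "frequent_hmrs.bed")
      write_bed(catalog$frequent_hmrs, p)
      add_output("catalog", "frequent_hmrs", p)
      for (t in catalog$tissues) {
        p <- file.path(config$out_dir, paste0("t_hmrs_", t, ".bed"))
        write_bed(catalog$t_hmrs[[t]], p)
        add_output("catalog", paste0("t_hmrs_", t), p)
      }
    }
    if ("dmr" %in% config$stages) {
      stage <- "dmr"
      series <- simulate_cancer_series(design, tissue = design$tissues[1],
                                       coverage_mean = config$coverage_mean,
                                       seed = config$seed + 300L)
      pa <- smooth_profile(series$normal, config$min_window_bp,
                           config$smooth_min_cpgs)
      pb <- smooth_profile(series$primary, config$min_window_bp,
                           config$smooth_min_cpgs)
      dmrs <- call_dmrs(pb, pa, min_consecutive = config$min_consecutive)
      p <- file.path(config$out_dir, "dmrs_primary_vs_normal.bed")
      write_bed(interval_set(as.data.frame(dmrs)), p)
      add_output("dmr", "dmrs_primary_vs_normal", p)
    }
    if ("cohort" %in% config$stages) {
      stage <- "cohort"
      sim <- do.call(simulate_beta_cohort,
                     c(list(design = design), config$cohort,
                       list(seed = config$seed + 400L)))
      islands <- sim$truth$islands
      c_islands <- interval_set(islands[islands$kind == "c",
                                        c("chrom", "start", "end")])
      summ <- hmr_beta_summary(c_islands, sim$betas,
                               min_probes = config$confirm_min_probes)
      confirmed <- confirm_hypomethylated(summ,
                                          max_beta = config$confirm_max_beta,
                                          min_probes = config$confirm_min_probes)
      sub <- summ
      sub$hmrs <- sub$hmrs[confirmed, , drop = FALSE]
      sub$mean_beta <- sub$mean_beta[confirmed, , drop = FALSE]
      events <- call_hypermethylation_events(sub, intensity = config$intensity,
                                             frequency = config$frequency)
      p <- file.path(config$out_dir, "hypermethylation_events.tsv")
      utils::write.table(events, p, sep = "\t", quote = FALSE, row.names = FALSE)
      add_output("cohort", "hypermethylation_events", p)
      cl <- cluster_samples(summ, dichotomize_at = config$dichotomize_at)
      p <- file.path(config$out_dir, "sample_clustering.tsv")
      ord <- data.frame(sample_id = cl$hclust$labels[cl$hclust$order],
                        order = seq_along(cl$hclust$order))
      utils::write.table(ord, p, sep = "\t", quote = FALSE, row.names = FALSE)
      add_output("cohort", "sample_clustering", p)
    }
    if ("mutex" %in% config$stages) {
      stage <- "mutex"
      excl <- list(set1 = 1:4)
      set.seed(config$seed + 499L)
      calls <- simulate_alteration_matrix(
        n_genes = 20L, n_samples = 100L, per_gene_rates = 0.06,
        burden_multipliers = stats::runif(100L, 0.5, 2),
        exclusive_sets = excl, seed = config$seed + 500L)
      res <- mutex_test(calls, rownames(calls)[excl$set1],
                        n_sims = config$mutex_n_sims,
                        seed = config$seed + 501L,
                        epsilon = config$mutex_epsilon)
      p <- file.path(config$out_dir, "mutex_result.json")
      jsonlite::write_json(
        list(gene_set = res$gene_set,
             observed_coverage = res$observed_coverage,
             null_mean = res$null_mean, null_sd = res$null_sd,
             z_score = res$z_score, empirical_p = res$empirical_p,
             n_sims = res$n_sims),
        p, auto_unbox = TRUE, digits = NA)
      add_output("mutex", "mutex_result", p)
    }
    TRUE
  }, error = function(e) e)
  if (inherits(result, "error")) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(result)), call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", length(manifest$outputs), " outputs")
  invisible(manifest)
}
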