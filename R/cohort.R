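#' Probe-level beta matrices with coordinates
#'
#' Container for array-style methylation data: a probes x samples matrix
#' of beta values in \[0, 1\] (missing allowed), probe genomic coordinates,
#' and per-sample metadata (`sample_id`, `label` e.g. tissue or cancer
#' type, `group` either `"normal"` or `"cancer"`).
#'
#' @param beta numeric matrix (probes x samples), rownames = probe ids.
#' @param probes data frame: `probe_id`, `chrom`, `pos` (0-based).
#' @param samples data frame: `sample_id`, `label`, `group`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, probes, samples) {
  stopifnot(is.matrix(beta),
            all(c("probe_id", "chrom", "pos") %in% names(probes)),
            all(c("sample_id", "label", "group") %in% names(samples)),
            nrow(beta) == nrow(probes), ncol(beta) == nrow(samples),
            all(samples$group %in% c("normal", "cancer")))
  vals <- beta[!is.na(beta)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("beta_matrix: beta values outside [0, 1]")
  rownames(beta) <- probes$probe_id
  colnames(beta) <- samples$sample_id
  structure(list(beta = beta, probes = probes, samples = samples),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples (%d normal, %d cancer)\n",
              nrow(x$beta), ncol(x$beta), sum(x$samples$group == "normal"),
              sum(x$samples$group == "cancer")))
  invisible(x)
}

#' Summarize beta values per catalog HMR
#'
#' Maps probes into HMR intervals (probe position in `[start, end)`) and
#' averages the non-missing betas per HMR per sample. HMRs with fewer than
#' `min_probes` probes are flagged unrepresented (but still summarized).
#'
#' @param catalog_hmrs `interval_set` of HMRs.
#' @param betas a [beta_matrix()].
#' @param min_probes representation threshold (default 1).
#' @return An object of class `hmr_beta_summary`: `hmrs` (coordinates,
#'   `n_probes`, `represented`), `mean_beta` (HMR x sample matrix) and
#'   `samples`.
#' @export
hmr_beta_summary <- function(catalog_hmrs, betas, min_probes = 1L) {
  stopifnot(inherits(betas, "beta_matrix"))
  if (nrow(betas$beta) == 0L) stop("hmr_beta_summary: beta matrix has no probes")
  h <- interval_set(catalog_hmrs)
  mean_beta <- matrix(NA_real_, nrow(h), ncol(betas$beta),
                      dimnames = list(NULL, colnames(betas$beta)))
  n_probes <- integer(nrow(h))
  for (i in seq_len(nrow(h))) {
    idx <- which(betas$probes$chrom == h$chrom[i] &
                 betas$probes$pos >= h$start[i] & betas$probes$pos < h$end[i])
    n_probes[i] <- length(idx)
    if (length(idx))
      mean_beta[i, ] <- colMeans(betas$beta[idx, , drop = FALSE], na.rm = TRUE)
  }
  mean_beta[is.nan(mean_beta)] <- NA_real_
  hmrs <- data.frame(h[, c("chrom", "start", "end")],
                     n_probes = n_probes,
                     represented = n_probes >= min_probes)
  if (!is.null(h$name)) hmrs$name <- h$name
  rownames(mean_beta) <- .hmr_id(hmrs)
  structure(list(hmrs = hmrs, mean_beta = mean_beta, samples = betas$samples),
            class = "hmr_beta_summary")
}

.hmr_id <- function(h) paste0(h$chrom, ":", h$start, "-", h$end)

.sample_idx <- function(summary, which_samples, group) {
  if (is.null(which_samples))
    which(summary$samples$group == group)
  else
    match(which_samples, summary$samples$sample_id)
}

#' Confirm catalog HMRs as hypomethylated on the array
#'
#' An HMR is confirmed when it carries at least `min_probes` probes and its
#' mean beta is at most `max_beta` in every normal sample (the ">5 probes,
#' average methylation <= 30%" confirmation rule, with >5 read as >= 6).
#'
#' @param summary an [hmr_beta_summary()].
#' @param normal_samples sample ids; default all samples with
#'   `group == "normal"`.
#' @param max_beta confirmation ceiling (default 0.30).
#' @param min_probes minimum probes (default 6).
#' @return Logical vector, one per HMR.
#' @export
confirm_hypomethylated <- function(summary, normal_samples = NULL,
                                   max_beta = 0.30, min_probes = 6L) {
  idx <- .sample_idx(summary, normal_samples, "normal")
  stopifnot(length(idx) >= 1L, !anyNA(idx))
  mb <- summary$mean_beta[, idx, drop = FALSE]
  ok_beta <- apply(mb, 1L, function(v) all(!is.na(v)) && all(v <= max_beta))
  unname(summary$hmrs$n_probes >= min_probes & ok_beta)
}

#' Call frequent hypermethylation events across a cancer cohort
#'
#' An HMR is an event when the fraction of cancer samples whose mean beta
#' strictly exceeds `intensity` is at least `frequency` (the ">33% in at
#' least 25% of the samples" rule).
#'
#' @param summary an [hmr_beta_summary()] (typically pre-filtered to
#'   confirmed hypomethylated HMRs).
#' @param cancer_samples sample ids; default all `group == "cancer"`.
#' @param intensity beta intensity threshold (default 0.33).
#' @param frequency sample-fraction threshold (default 0.25).
#' @return Data frame: `hmr`, `event_frequency`, `is_event`; HMRs with no
#'   non-missing cancer beta are excluded and counted in attribute
#'   `"n_excluded"`.
#' @export
call_hypermethylation_events <- function(summary, cancer_samples = NULL,
                                         intensity = 0.33, frequency = 0.25) {
  idx <- .sample_idx(summary, cancer_samples, "cancer")
  stopifnot(length(idx) >= 1L, !anyNA(idx))
  mb <- summary$mean_beta[, idx, drop = FALSE]
  n_obs <- rowSums(!is.na(mb))
  f <- rowSums(mb > intensity, na.rm = TRUE) / n_obs
  keep <- n_obs > 0L
  res <- data.frame(hmr = rownames(summary$mean_beta)[keep],
                    event_frequency = f[keep],
                    is_event = f[keep] >= frequency,
                    stringsAsFactors = FALSE)
  attr(res, "n_excluded") <- sum(!keep)
  res
}

#' Positive-selection candidate HMRs
#'
#' Promoter HMRs with recurrent high-intensity hypermethylation: mean beta
#' strictly above `intensity` in strictly more than `min_freq` of the
#' (optionally solid-tumor-only) cancer samples, with at least `min_probes`
#' probes. High intensity reflects clonal expansion of the altered cells,
#' the signature of positively selected epigenetic driver events.
#'
#' @param summary an [hmr_beta_summary()].
#' @param cancer_samples sample ids; default all `group == "cancer"`.
#' @param promoter_flags logical, one per HMR of `summary`.
#' @param intensity beta threshold (default 0.50).
#' @param min_freq recurrence fraction, strict (default 0.01).
#' @param min_probes minimum probes (default 2).
#' @param solid_only restrict the denominator to solid tumors.
#' @param solid_types labels counted as solid (required when `solid_only`).
#' @return Data frame of candidates: `hmr`, `frequency`, `n_probes`.
#' @export
positive_selection_candidates <- function(summary, cancer_samples = NULL,
                                          promoter_flags, intensity = 0.50,
                                          min_freq = 0.01, min_probes = 2L,
                                          solid_only = FALSE,
                                          solid_types = NULL) {
  stopifnot(length(promoter_flags) == nrow(summary$hmrs))
  idx <- .sample_idx(summary, cancer_samples, "cancer")
  if (solid_only) {
    stopifnot(!is.null(solid_types))
    idx <- idx[summary$samples$label[idx] %in% solid_types]
  }
  stopifnot(length(idx) >= 1L)
  mb <- summary$mean_beta[, idx, drop = FALSE]
  n_obs <- rowSums(!is.na(mb))
  f <- rowSums(mb > intensity, na.rm = TRUE) / pmax(n_obs, 1L)
  is_cand <- promoter_flags & summary$hmrs$n_probes >= min_probes &
    n_obs > 0L & f > min_freq
  data.frame(hmr = rownames(summary$mean_beta)[is_cand],
             frequency = f[is_cand],
             n_probes = summary$hmrs$n_probes[is_cand],
             stringsAsFactors = FALSE)
}

#' Validate tissue-specific HMRs by threshold sweep
#'
#' For each threshold, a (t-HMR, sample) pair scores a true positive when
#' the sample matches the t-HMR's tissue and the mean beta lies below the
#' threshold, and a false positive when an unmatched sample lies below the
#' threshold. Sensitivity and false positive rate are swept over the grid
#' and summarized by the trapezoidal area under the ROC curve.
#'
#' @param summary an [hmr_beta_summary()] over the t-HMRs.
#' @param t_hmr_tissue_labels tissue label per HMR of `summary`.
#' @param sample_tissue_labels tissue label per sample of `summary`
#'   (default: the summary's `label` column).
#' @param threshold_grid beta thresholds (default `seq(0, 1, 0.02)`).
#' @return An object of class `catalog_validation`: `thresholds`,
#'   `sensitivity`, `fpr`, `auc`, pair counts.
#' @export
validate_catalog <- function(summary, t_hmr_tissue_labels,
                             sample_tissue_labels = NULL,
                             threshold_grid = seq(0, 1, by = 0.02)) {
  if (is.null(sample_tissue_labels)) sample_tissue_labels <- summary$samples$label
  stopifnot(length(t_hmr_tissue_labels) == nrow(summary$mean_beta),
            length(sample_tissue_labels) == ncol(summary$mean_beta))
  matched <- outer(t_hmr_tissue_labels, sample_tissue_labels, "==")
  mb <- summary$mean_beta
  ok <- !is.na(mb)
  n_tp_pairs <- sum(matched & ok)
  n_fp_pairs <- sum(!matched & ok)
  if (n_tp_pairs == 0L) stop("validate_catalog: no matched (t-HMR, sample) pairs")
  sens <- fpr <- numeric(length(threshold_grid))
  for (i in seq_along(threshold_grid)) {
    below <- ok & mb < threshold_grid[i]
    sens[i] <- sum(below & matched) / n_tp_pairs
    fpr[i] <- sum(below & !matched) / n_fp_pairs
  }
  o <- order(fpr, sens)
  xs <- c(0, fpr[o], 1); ys <- c(0, sens[o], 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(list(thresholds = threshold_grid, sensitivity = sens, fpr = fpr,
                 auc = auc, n_matched_pairs = n_tp_pairs,
                 n_unmatched_pairs = n_fp_pairs),
            class = "catalog_validation")
}

#' @export
print.catalog_validation <- function(x, ...) {
  cat(sprintf("<catalog_validation> AUC = %.3f over %d thresholds (%d matched / %d unmatched pairs)\n",
              x$auc, length(x$thresholds), x$n_matched_pairs, x$n_unmatched_pairs))
  invisible(x)
}

#' Cluster samples on dichotomized HMR methylation
#'
#' Mean betas are dichotomized at `dichotomize_at`, samples are compared by
#' Jaccard distance on their binary HMR vectors, and agglomerated with
#' Ward's method (`hclust(method = "ward.D2")`).
#'
#' @param summary an [hmr_beta_summary()] with >= 3 samples and >= 2 HMRs.
#' @param dichotomize_at beta cutoff (default 0.33).
#' @param k optional number of flat clusters to cut.
#' @return List with `hclust`, `labels` (when `k` given), `binary` matrix
#'   and `distance`. Identical binary vectors across all samples trigger a
#'   warning (single trivial cluster).
#' @export
cluster_samples <- function(summary, dichotomize_at = 0.33, k = NULL) {
  stopifnot(ncol(summary$mean_beta) >= 3L, nrow(summary$mean_beta) >= 2L)
  B <- summary$mean_beta > dichotomize_at
  ns <- ncol(B)
  D <- matrix(0, ns, ns, dimnames = list(colnames(B), colnames(B)))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ok <- !is.na(B[, i]) & !is.na(B[, j])
    both <- sum(B[ok, i] & B[ok, j]); either <- sum(B[ok, i] | B[ok, j])
    D[i, j] <- D[j, i] <- if (either == 0L) 0 else 1 - both / either
  }
  if (all(D == 0))
    warning("cluster_samples: all samples identical after dichotomization; single cluster")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- if (is.null(k)) NULL else stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels, binary = B, distance = stats::as.dist(D))
}
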