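#' Build the common / frequent / tissue-specific HMR catalog
#'
#' Across a panel of normal tissues:
#' \itemize{
#'   \item common HMRs (c-HMRs) are the genomic regions strictly covered by
#'     HMRs in every tissue, with resulting fragments merged when at most
#'     `merge_gap_bp` apart;
#'   \item tissue-specific HMRs (t-HMRs) of a tissue are its HMRs sharing
#'     zero bases with any other tissue's HMRs;
#'   \item frequent HMRs are merged regions covered by HMRs in strictly more
#'     than `frequent_fraction` of the tissues, excluding any region that
#'     overlaps a c-HMR.
#' }
#'
#' @param per_tissue_hmrs named list (tissue -> interval set / `hmr_set`);
#'   at least two tissues, each internally non-overlapping.
#' @param merge_gap_bp maximal genomic distance closed by the merge step
#'   (default 100).
#' @param frequent_fraction fraction of tissues defining "frequent"
#'   (strict inequality; default 0.5).
#' @return An object of class `hmr_catalog`: list with `tissues`,
#'   `per_tissue`, `c_hmrs`, `frequent_hmrs`, `t_hmrs` and `params`.
#'   Partition invariants (t-HMRs disjoint from all other tissues, frequent
#'   disjoint from common) are asserted on every build.
#' @export
build_catalog <- function(per_tissue_hmrs, merge_gap_bp = 100L,
                          frequent_fraction = 0.5) {
  if (length(per_tissue_hmrs) < 2L)
    stop("build_catalog: need >= 2 tissues")
  if (is.null(names(per_tissue_hmrs)) || any(!nzchar(names(per_tissue_hmrs))))
    stop("build_catalog: per_tissue_hmrs must be a named list")
  sets <- lapply(per_tissue_hmrs, function(s)
    interval_set(as.data.frame(s)[, c("chrom", "start", "end")]))
  tissues <- names(sets)
  n <- length(sets)

  c_hmrs <- merge_intervals(Reduce(intersect_intervals, sets), merge_gap_bp)

  t_hmrs <- lapply(tissues, function(t) {
    others <- merge_intervals(interval_set(
      do.call(rbind, lapply(sets[setdiff(tissues, t)], as.data.frame))), 0L)
    keep <- !overlap_any(sets[[t]], others)
    sets[[t]][keep, , drop = FALSE]
  })
  names(t_hmrs) <- tissues

  k <- floor(frequent_fraction * n) + 1L   # strictly more than the fraction
  freq_raw <- merge_intervals(covered_by_at_least(sets, k), merge_gap_bp)
  frequent <- freq_raw[!overlap_any(freq_raw, c_hmrs), , drop = FALSE]

  # partition algebra, asserted on every build
  for (t in tissues) {
    others <- interval_set(
      do.call(rbind, lapply(sets[setdiff(tissues, t)], as.data.frame)))
    if (.shared_bp(t_hmrs[[t]], others) != 0)
      stop("build_catalog: t-HMR invariant violated for tissue ", t)
  }
  if (.shared_bp(frequent, c_hmrs) != 0)
    stop("build_catalog: frequent/common disjointness invariant violated")

  structure(list(tissues = tissues, per_tissue = sets, c_hmrs = c_hmrs,
                 frequent_hmrs = interval_set(frequent), t_hmrs = t_hmrs,
                 params = list(merge_gap_bp = merge_gap_bp,
                               frequent_fraction = frequent_fraction)),
            class = "hmr_catalog")
}

#' @export
print.hmr_catalog <- function(x, ...) {
  cat(sprintf("<hmr_catalog> %d tissues: %s\n", length(x$tissues),
              paste(x$tissues, collapse = ", ")))
  cat(sprintf("  c-HMRs: %d (%.0f bp); frequent: %d; t-HMRs: %s\n",
              nrow(x$c_hmrs), total_bp(x$c_hmrs), nrow(x$frequent_hmrs),
              paste(vapply(x$t_hmrs, nrow, 0L), collapse = "/")))
  invisible(x)
}

#' Co-activation of t-HMRs with proximal hypomethylated promoters
#'
#' Each t-HMR is assigned to the nearest gene promoter within
#' `proximity_bp`; unassignable t-HMRs are skipped and counted. Entry
#' (i, j) of the result is the fraction of tissue-i t-HMRs whose nearest
#' gene's promoter is hypomethylated (treated as potentially active) in
#' tissue j.
#'
#' @param catalog an `hmr_catalog`.
#' @param promoters data frame: `gene`, `chrom`, `start`, `end`.
#' @param promoter_state character matrix (tissues x genes) with entries
#'   `"hypomethylated"` or `"methylated"`.
#' @param proximity_bp maximum HMR-to-promoter distance (default 10000,
#'   the proximal-TSS convention).
#' @return Numeric matrix (t-HMR tissue x evaluation tissue) with attribute
#'   `"n_skipped"`; rows for tissues with no assignable t-HMR are `NA` and
#'   flagged via attribute `"undefined_rows"`.
#' @export
co_activation <- function(catalog, promoters, promoter_state,
                          proximity_bp = 10000L) {
  tissues <- catalog$tissues
  ev_tissues <- rownames(promoter_state)
  stopifnot(!is.null(ev_tissues), !is.null(colnames(promoter_state)))
  mat <- matrix(NA_real_, length(tissues), length(ev_tissues),
                dimnames = list(tissues, ev_tissues))
  n_skipped <- 0L
  undefined <- character(0)
  for (t in tissues) {
    th <- catalog$t_hmrs[[t]]
    genes <- character(0)
    for (i in seq_len(nrow(th))) {
      same <- promoters$chrom == th$chrom[i]
      if (!any(same)) { n_skipped <- n_skipped + 1L; next }
      pr <- promoters[same, , drop = FALSE]
      # distance between half-open intervals (0 when overlapping)
      d <- pmax(0, pmax(pr$start - th$end[i], th$start[i] - pr$end))
      j <- which.min(d)
      if (d[j] > proximity_bp) { n_skipped <- n_skipped + 1L; next }
      genes <- c(genes, pr$gene[j])
    }
    if (!length(genes)) { undefined <- c(undefined, t); next }
    for (e in ev_tissues)
      mat[t, e] <- mean(promoter_state[e, genes] == "hypomethylated")
  }
  attr(mat, "n_skipped") <- n_skipped
  attr(mat, "undefined_rows") <- undefined
  mat
}

#' Composite methylation profile around HMR centers
#'
#' CpGs of each sample are mapped to their offset from the nearest HMR
#' center, binned, and averaged, producing the canonical
#' "well around the HMR center" composite view.
#'
#' @param hmrs `interval_set` of HMRs.
#' @param samples list of [methylome()] objects.
#' @param flank_bp half-width of the displayed window (default 2000).
#' @param bin_bp bin width in bp (default 4).
#' @return Matrix (bins x samples) of mean levels, `NA` for bins without
#'   CpGs; bin center offsets as rownames and attribute `"offset"`.
#' @export
composite_profile <- function(hmrs, samples, flank_bp = 2000L, bin_bp = 4L) {
  hmrs <- interval_set(hmrs)
  stopifnot(nrow(hmrs) > 0, length(samples) > 0)
  breaks <- seq(-flank_bp, flank_bp, by = bin_bp)
  centers_off <- breaks[-length(breaks)] + bin_bp / 2
  ids <- vapply(seq_along(samples), function(i) {
    id <- attr(samples[[i]], "sample_id")
    if (is.null(id)) paste0("sample", i) else id
  }, character(1))
  out <- matrix(NA_real_, length(centers_off), length(samples),
                dimnames = list(sprintf("%g", centers_off), ids))
  hmr_center <- floor((hmrs$start + hmrs$end) / 2)
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    acc <- rep(0, length(centers_off)); cnt <- rep(0L, length(centers_off))
    for (i in seq_len(nrow(hmrs))) {
      idx <- which(s$chrom == hmrs$chrom[i] &
                   s$pos >= hmr_center[i] - flank_bp &
                   s$pos < hmr_center[i] + flank_bp)
      if (!length(idx)) next
      off <- s$pos[idx] - hmr_center[i]
      b <- findInterval(off, breaks, rightmost.closed = FALSE)
      for (j in seq_along(idx)) {
        acc[b[j]] <- acc[b[j]] + s$level[idx[j]]
        cnt[b[j]] <- cnt[b[j]] + 1L
      }
    }
    out[cnt > 0L, si] <- acc[cnt > 0L] / cnt[cnt > 0L]
  }
  attr(out, "offset") <- centers_off
  out
}

#' Interval enrichment by tiled Fisher's exact test
#'
#' The universe is cut into `tile_bp` tiles; each tile is classified by
#' whether its midpoint falls in the query and/or the annotation, giving a
#' 2x2 table tested with Fisher's exact test. Tiling avoids the
#' pseudo-replication of counting single bases as independent trials.
#'
#' @param query,annotation,universe `interval_set`s; query must lie within
#'   the universe by base coverage.
#' @param tile_bp tile width (default 100).
#' @return List with `table` (2x2 counts), `odds_ratio` (sample OR),
#'   `p_value` (two-sided Fisher) and `degenerate` (TRUE when a margin is
#'   empty or full, making the OR undefined/infinite).
#' @export
interval_enrichment <- function(query, annotation, universe, tile_bp = 100L) {
  query <- interval_set(query); annotation <- interval_set(annotation)
  universe <- merge_intervals(universe, 0L)
  if (!nrow(query) || !nrow(annotation))
    stop("interval_enrichment: empty query or annotation")
  if (.shared_bp(query, universe) != total_bp(query))
    stop("interval_enrichment: query not contained in universe")
  mids <- unlist(lapply(seq_len(nrow(universe)), function(i) {
    ts <- seq(universe$start[i], universe$end[i] - 1L, by = tile_bp)
    te <- pmin(ts + tile_bp, universe$end[i])
    floor((ts + te) / 2)
  }))
  chrs <- rep(universe$chrom, vapply(seq_len(nrow(universe)), function(i)
    length(seq(universe$start[i], universe$end[i] - 1L, by = tile_bp)), 0L))
  pts <- interval_set(chrs, mids, mids + 1L)
  in_q <- overlap_any(pts, query)
  in_a <- overlap_any(pts, annotation)
  tab <- matrix(c(sum(in_q & in_a), sum(in_q & !in_a),
                  sum(!in_q & in_a), sum(!in_q & !in_a)), 2, 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"),
                                annotation = c("in", "out")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = if (degenerate) NA_real_ else or,
       p_value = p, degenerate = degenerate)
}
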