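#' Call differentially methylated regions from smoothed profiles
#'
#' A CpG separates the two samples when the 95% confidence bands of their
#' smoothed profiles are disjoint: "hyper" when `a`'s lower bound exceeds
#' `b`'s upper bound, "hypo" when `a`'s upper bound lies below `b`'s lower
#' bound. Maximal same-direction runs of at least `min_consecutive`
#' separated CpGs (the "more than five consecutive CpGs" rule, read
#' literally as at least 6) become DMRs spanning the first to the last CpG
#' of the run (end = last CpG + 2, half-open).
#'
#' Positions present in only one profile are dropped before calling, with
#' a message; runs never span chromosome boundaries.
#'
#' @param a,b `smoothed_profile` objects (direction is the sign of a - b).
#' @param min_consecutive minimum run length (default 6).
#' @return A data frame of class `dmr_set`: `chrom`, `start`, `end`,
#'   `direction` (`"hyper"`/`"hypo"`), `n_cpg`, `mean_delta`.
#' @export
call_dmrs <- function(a, b, min_consecutive = 6L) {
  ka <- paste(a$chrom, a$pos); kb <- paste(b$chrom, b$pos)
  shared <- intersect(ka, kb)
  dropped <- (length(ka) - length(shared)) + (length(kb) - length(shared))
  if (dropped > 0)
    message(sprintf("call_dmrs: dropped %d position(s) absent from one profile", dropped))
  a <- a[ka %in% shared, , drop = FALSE]
  b <- b[match(paste(a$chrom, a$pos), kb), , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), n_cpg = integer(),
                      mean_delta = numeric())
  class(empty) <- unique(c("dmr_set", class(empty)))
  if (nrow(a) < min_consecutive) {
    warning("call_dmrs: fewer shared CpGs than min_consecutive; no calls possible")
    return(empty)
  }
  state <- integer(nrow(a))
  state[a$ci_low > b$ci_high] <- 1L
  state[a$ci_high < b$ci_low] <- -1L
  delta <- a$level_hat - b$level_hat
  out <- list()
  for (idx in split(seq_len(nrow(a)), a$chrom)) {
    st <- state[idx]
    run_id <- cumsum(c(TRUE, diff(st) != 0))
    for (r in split(seq_along(st), run_id)) {
      if (st[r[1L]] == 0L || length(r) < min_consecutive) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = a$chrom[idx[1L]],
        start = a$pos[idx][r[1L]],
        end = a$pos[idx][r[length(r)]] + 2L,
        direction = if (st[r[1L]] > 0L) "hyper" else "hypo",
        n_cpg = length(r),
        mean_delta = mean(delta[idx][r]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- unique(c("dmr_set", class(res)))
  res
}

#' Genome-wide cross-sample methylation statistics
#'
#' Restricts to CpGs covered by at least `min_coverage` reads in every
#' sample, then reports the per-CpG standard deviation of levels across
#' samples, the fraction of CpGs whose s.d. exceeds `sd_threshold`, and
#' each sample's mean level over the shared CpG set.
#'
#' @param samples list of >= 2 [methylome()] objects.
#' @param sd_threshold variability threshold on the per-CpG s.d.
#'   (default 0.1).
#' @param min_coverage minimum per-sample read depth (default 5).
#' @return List with `n_cpgs`, `fraction_sd_gt`, `mean_level` (named per
#'   sample), `sd_threshold` and the per-CpG `sd` vector.
#' @export
global_stats <- function(samples, sd_threshold = 0.1, min_coverage = 5L) {
  stopifnot(length(samples) >= 2L)
  keys <- lapply(samples, function(s) paste(s$chrom, s$pos))
  shared <- Reduce(intersect, keys)
  if (!length(shared)) stop("global_stats: no CpGs shared by all samples")
  lv <- cov_ok <- NULL
  levels <- sapply(seq_along(samples), function(i) {
    ix <- match(shared, keys[[i]])
    ok <- samples[[i]]$total[ix] >= min_coverage
    ifelse(ok, samples[[i]]$level[ix], NA_real_)
  })
  keep <- stats::complete.cases(levels)
  if (!any(keep)) stop("global_stats: no CpGs pass the coverage filter in all samples")
  levels <- levels[keep, , drop = FALSE]
  sdv <- apply(levels, 1L, stats::sd)
  ids <- vapply(seq_along(samples), function(i) {
    id <- attr(samples[[i]], "sample_id")
    if (is.null(id)) paste0("sample", i) else id
  }, character(1))
  means <- colMeans(levels)
  names(means) <- ids
  list(n_cpgs = nrow(levels), fraction_sd_gt = mean(sdv > sd_threshold),
       mean_level = means, sd_threshold = sd_threshold, sd = sdv)
}

#' Correlation between neighboring CpG methylation levels
#'
#' Pearson correlation over (level_i, level_i+1) pairs of consecutive CpGs
#' on the same chromosome at most `max_distance_bp` apart. Loss of this
#' correlation is a signature of the disordered hypomethylation of cancer
#' methylomes.
#'
#' @param sample a [methylome()].
#' @param max_distance_bp maximum pair distance in bp (default 1000).
#' @param breaks optional distance-bin breaks; when given, a per-bin
#'   correlation data frame is returned instead.
#' @return Pearson r (scalar), or a data frame (`bin`, `n_pairs`, `r`) when
#'   `breaks` is supplied. Zero variance in either pair member yields `NA`
#'   with a warning, never a silent 0.
#' @export
neighbor_correlation <- function(sample, max_distance_bp = 1000L, breaks = NULL) {
  x <- y <- d <- numeric(0)
  for (idx in split(seq_len(nrow(sample)), sample$chrom)) {
    if (length(idx) < 2L) next
    p <- sample$pos[idx]; lv <- sample$level[idx]
    dd <- diff(p)
    ok <- dd <= max_distance_bp
    x <- c(x, lv[-length(lv)][ok]); y <- c(y, lv[-1L][ok]); d <- c(d, dd[ok])
  }
  if (length(x) < 10L)
    stop("neighbor_correlation: fewer than 10 adjacent pairs within max_distance_bp")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("neighbor_correlation: zero variance; correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  if (is.null(breaks)) return(safe_cor(x, y))
  b <- cut(d, breaks = breaks, include.lowest = TRUE)
  do.call(rbind, lapply(levels(b), function(lv_b) {
    i <- which(b == lv_b)
    data.frame(bin = lv_b, n_pairs = length(i),
               r = if (length(i) >= 10L) safe_cor(x[i], y[i]) else NA_real_)
  }))
}

#' Compare regional methylation between two sample groups
#'
#' Computes per-region per-sample mean CpG methylation and a two-sided
#' two-sample Student's t-test (equal variances) per region, e.g. for
#' repeat-element families between normal and cancer methylomes.
#'
#' @param samples_a,samples_b lists of >= 2 [methylome()] objects.
#' @param regions `interval_set` of regions.
#' @return Data frame with one row per evaluable region: coordinates,
#'   `mean_a`, `mean_b`, `t`, `p`; regions without covered CpGs in either
#'   group are excluded and counted in attribute `"n_excluded"`.
#' @export
interval_methylation_compare <- function(samples_a, samples_b, regions) {
  stopifnot(length(samples_a) >= 2L, length(samples_b) >= 2L)
  regions <- interval_set(regions)
  region_means <- function(s) {
    vapply(seq_len(nrow(regions)), function(i) {
      idx <- which(s$chrom == regions$chrom[i] &
                   s$pos >= regions$start[i] & s$pos < regions$end[i])
      if (!length(idx)) NA_real_ else mean(s$level[idx])
    }, numeric(1))
  }
  ma <- vapply(samples_a, region_means, numeric(nrow(regions)))
  mb <- vapply(samples_b, region_means, numeric(nrow(regions)))
  if (nrow(regions) == 1L) {
    dim(ma) <- c(1L, length(samples_a))
    dim(mb) <- c(1L, length(samples_b))
  }
  ok <- rowSums(!is.na(ma)) >= 2L & rowSums(!is.na(mb)) >= 2L
  res <- do.call(rbind, lapply(which(ok), function(i) {
    va <- ma[i, ][!is.na(ma[i, ])]; vb <- mb[i, ][!is.na(mb[i, ])]
    tt <- if (stats::sd(c(va, vb)) == 0) list(statistic = NA_real_, p.value = NA_real_)
          else stats::t.test(va, vb, var.equal = TRUE)
    data.frame(chrom = regions$chrom[i], start = regions$start[i],
               end = regions$end[i], mean_a = mean(va), mean_b = mean(vb),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_a = numeric(), mean_b = numeric(),
                      t = numeric(), p = numeric())
  attr(res, "n_excluded") <- sum(!ok)
  res
}
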