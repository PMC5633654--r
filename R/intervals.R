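#' Genomic interval sets
#'
#' An `interval_set` is a data frame with columns `chrom`, `start`, `end`
#' holding 0-based half-open genomic intervals, sorted by
#' (`chrom`, `start`, `end`). All interval algebra in the package
#' (intersection, gap-closing merge, overlap queries) operates on this
#' representation; `IRanges` provides the underlying machinery.
#'
#' @param chrom character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end` (extra columns are preserved).
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @return A data frame of class `interval_set`, sorted, with
#'   `start < end` and non-negative coordinates.
#' @examples
#' interval_set(c("chr1", "chr1"), c(0L, 150L), c(100L, 200L))
#' @export
interval_set <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    x <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  } else {
    x <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start),
                    end = as.integer(end),
                    stringsAsFactors = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (nrow(x)) {
    if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$chrom)))
      stop("interval_set: missing coordinates")
    if (any(x$start < 0L)) stop("interval_set: negative coordinates")
    if (any(x$start >= x$end)) stop("interval_set: start must be < end")
    o <- order(x$chrom, x$start, x$end)
    x <- x[o, , drop = FALSE]
  }
  rownames(x) <- NULL
  class(x) <- unique(c("interval_set", class(x)))
  x
}

.empty_intervals <- function() interval_set(character(), integer(), integer())

# split to per-chromosome IRanges (1-based closed)
.by_chrom_ir <- function(x) {
  if (!nrow(x)) return(list())
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
}

.ir_to_df <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = BiocGenerics::start(ir) - 1L,
             end = BiocGenerics::end(ir),
             stringsAsFactors = FALSE)
}

#' Base-level intersection of two interval sets
#'
#' Returns the exact set of bases covered by both `a` and `b`, as a
#' non-overlapping sorted `interval_set`.
#'
#' @param a,b `interval_set` objects (or coercible data frames).
#' @return An `interval_set` covering exactly the shared bases.
#' @export
intersect_intervals <- function(a, b) {
  a <- interval_set(a); b <- interval_set(b)
  ia <- .by_chrom_ir(a); ib <- .by_chrom_ir(b)
  shared <- intersect(names(ia), names(ib))
  out <- lapply(shared, function(ch)
    .ir_to_df(IRanges::intersect(ia[[ch]], ib[[ch]]), ch))
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out)) return(.empty_intervals())
  interval_set(do.call(rbind, out))
}

#' Merge intervals, closing gaps up to a maximum distance
#'
#' Unions intervals on the same chromosome that overlap or whose gap is
#' at most `max_gap` base pairs; the output is non-overlapping and any
#' remaining gap between consecutive intervals exceeds `max_gap`.
#'
#' @param a an `interval_set`.
#' @param max_gap non-negative integer gap (bp) to close; `0` merges only
#'   touching/overlapping intervals.
#' @return A merged `interval_set`.
#' @export
merge_intervals <- function(a, max_gap = 0L) {
  stopifnot(max_gap >= 0L)
  a <- interval_set(a)
  ia <- .by_chrom_ir(a)
  out <- lapply(names(ia), function(ch)
    .ir_to_df(IRanges::reduce(ia[[ch]], min.gapwidth = as.integer(max_gap) + 1L), ch))
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out)) return(.empty_intervals())
  interval_set(do.call(rbind, out))
}

#' Flag intervals of one set overlapping any interval of another
#'
#' @param a query `interval_set`; flags are returned in the (sorted) row
#'   order of `interval_set(a)`.
#' @param b subject `interval_set`.
#' @return Logical vector, one per interval of `a`: `TRUE` iff the interval
#'   shares at least one base with some interval of `b` (half-open; merely
#'   touching intervals do not overlap).
#' @export
overlap_any <- function(a, b) {
  a <- interval_set(a); b <- interval_set(b)
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  ib <- .by_chrom_ir(b)
  flags <- rep(FALSE, nrow(a))
  sp <- split(seq_len(nrow(a)), a$chrom)
  for (ch in names(sp)) {
    if (is.null(ib[[ch]])) next
    i <- sp[[ch]]
    ia <- IRanges::IRanges(start = a$start[i] + 1L, end = a$end[i])
    flags[i] <- IRanges::overlapsAny(ia, ib[[ch]])
  }
  flags
}

#' Bases covered by at least k of several interval sets
#'
#' @param sets list of `interval_set` objects.
#' @param k minimum number of sets covering a base.
#' @return An `interval_set` of the bases covered by >= k sets.
#' @export
covered_by_at_least <- function(sets, k) {
  stopifnot(length(sets) >= 1L, k >= 1L)
  # collapse each set first so internal overlaps count once
  all_df <- do.call(rbind, lapply(sets, function(s) {
    s <- merge_intervals(interval_set(s), 0L)
    as.data.frame(s)[, c("chrom", "start", "end")]
  }))
  if (!nrow(all_df)) return(.empty_intervals())
  pooled <- interval_set(all_df)
  ia <- .by_chrom_ir(pooled)
  out <- lapply(names(ia), function(ch) {
    cov <- IRanges::coverage(ia[[ch]])
    sl <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
    .ir_to_df(sl, ch)
  })
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out)) return(.empty_intervals())
  interval_set(do.call(rbind, out))
}

#' Total bases covered by an interval set
#' @param a an `interval_set` (overlaps are collapsed before counting).
#' @return Integer number of covered bases.
#' @export
total_bp <- function(a) {
  a <- merge_intervals(a, 0L)
  if (!nrow(a)) return(0)
  sum(as.numeric(a$end - a$start))
}

# bases shared by two sets (internal, used by catalog invariant checks)
.shared_bp <- function(a, b) total_bp(intersect_intervals(a, b))

#' Read a BED file as an interval set
#'
#' Standard BED semantics: 0-based half-open, tab-separated, first three
#' columns `chrom`, `start`, `end`; additional columns are kept as
#' `name`, `score`, `strand` when present.
#'
#' @param path file path.
#' @return An `interval_set`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(.empty_intervals())
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  extras <- c("name", "score", "strand")
  if (ncol(x) > 3L)
    names(x)[4:min(6L, ncol(x))] <- extras[seq_len(min(3L, ncol(x) - 3L))]
  interval_set(x)
}

#' Write an interval set as BED
#'
#' @param a an `interval_set`; extra columns beyond `chrom`, `start`, `end`
#'   are written as BED columns 4+ in their existing order.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(a, path) {
  a <- interval_set(a)
  core <- c("chrom", "start", "end")
  cols <- c(core, setdiff(names(a), core))
  utils::write.table(a[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
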