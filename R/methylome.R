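#' Per-CpG methylome tables
#'
#' A `methylome` is a data frame with one row per CpG site and columns
#' `chrom`, `pos` (0-based position of the CpG cytosine), `meth`
#' (reads supporting methylation), `total` (total reads, >= 1) and the
#' derived `level = meth/total`. Rows are sorted by (`chrom`, `pos`) with
#' no duplicate positions. Sample metadata travel as attributes.
#'
#' @param sites data frame with columns `chrom`, `pos`, `meth`, `total`.
#' @param sample_id,tissue sample identifier and tissue label.
#' @param status one of `"normal"`, `"cancer_primary"`,
#'   `"cancer_cell_line"`, `"metastasis"`.
#' @return A data frame of class `methylome`.
#' @export
methylome <- function(sites, sample_id = "sample", tissue = "tissue",
                      status = c("normal", "cancer_primary",
                                 "cancer_cell_line", "metastasis")) {
  status <- match.arg(status)
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(sites)))
  x <- data.frame(chrom = as.character(sites$chrom),
                  pos = as.integer(sites$pos),
                  meth = as.integer(sites$meth),
                  total = as.integer(sites$total),
                  stringsAsFactors = FALSE)
  if (nrow(x)) {
    if (any(is.na(x$pos)) || any(is.na(x$meth)) || any(is.na(x$total)))
      stop("methylome: missing values in site table")
    if (any(x$total < 1L)) stop("methylome: total read count must be >= 1")
    if (any(x$meth < 0L | x$meth > x$total))
      stop("methylome: methylated count outside [0, total]")
    o <- order(x$chrom, x$pos)
    if (is.unsorted(o)) x <- x[o, , drop = FALSE]
    if (anyDuplicated(paste(x$chrom, x$pos)))
      stop("methylome: duplicate CpG positions")
  }
  x$level <- ifelse(x$total > 0L, x$meth / x$total, NA_real_)
  rownames(x) <- NULL
  attr(x, "sample_id") <- sample_id
  attr(x, "tissue") <- tissue
  attr(x, "status") <- status
  class(x) <- unique(c("methylome", class(x)))
  x
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s (%s, %s): %d CpG sites on %d chromosome(s)\n",
              attr(x, "sample_id"), attr(x, "tissue"), attr(x, "status"),
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    cat(sprintf("  mean methylation level: %.3f; mean coverage: %.1fx\n",
                mean(x$level), mean(x$total)))
  }
  invisible(x)
}

#' Read a per-CpG methylation call table
#'
#' Supported dialects:
#' \describe{
#'   \item{`bismark_cov`}{Bismark coverage format: `chrom`, `start` (1-based,
#'     inclusive), `end`, `%methylation`, `count_methylated`,
#'     `count_unmethylated`. Positions are converted to 0-based.}
#'   \item{`bedgraph_counts`}{bedGraph-style: `chrom`, `start` (0-based),
#'     `end`, `%methylation`, `count_methylated`, `count_unmethylated`.}
#' }
#' Rows with zero total coverage are dropped (a message reports how many);
#' unsorted input is sorted with a message; duplicate positions are an error.
#'
#' @param path file path.
#' @param dialect `"bismark_cov"` or `"bedgraph_counts"`.
#' @param sample_id,tissue,status sample metadata stored on the result.
#' @return A `methylome`.
#' @export
read_cpg_table <- function(path, dialect = c("bismark_cov", "bedgraph_counts"),
                           sample_id = basename(path), tissue = "tissue",
                           status = "normal") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                meth = integer(), total = integer()),
                     sample_id, tissue, status))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop(sprintf("parse error at line %d: expected 6 tab-separated fields, got %d",
                 which(nf < 6L)[1L], nf[which(nf < 6L)[1L]]))
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  cm <- suppressWarnings(as.integer(m[, 5L]))
  cu <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(start) | is.na(cm) | is.na(cu))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-numeric coordinate or count", bad[1L]))
  pos <- if (dialect == "bismark_cov") start - 1L else start
  if (any(pos < 0L)) stop("parse error: negative position after coordinate conversion")
  total <- cm + cu
  drop0 <- total == 0L
  if (any(drop0))
    message(sprintf("read_cpg_table: dropped %d zero-coverage row(s)", sum(drop0)))
  chrom <- m[, 1L][!drop0]; pos <- pos[!drop0]
  cm <- cm[!drop0]; total <- total[!drop0]
  o <- order(chrom, pos)
  if (any(o != seq_along(o)))
    message("read_cpg_table: input not sorted by (chrom, pos); sorting")
  chrom <- chrom[o]; pos <- pos[o]; cm <- cm[o]; total <- total[o]
  if (anyDuplicated(paste(chrom, pos)))
    stop("read_cpg_table: duplicate CpG position in input")
  methylome(data.frame(chrom = chrom, pos = pos, meth = cm, total = total,
                       stringsAsFactors = FALSE),
            sample_id, tissue, status)
}

#' Write a methylome as a per-CpG call table
#'
#' Inverse of [read_cpg_table()]: the written file round-trips through the
#' same dialect to an identical table.
#'
#' @param x a `methylome`.
#' @param path output file path.
#' @param dialect `"bismark_cov"` or `"bedgraph_counts"`.
#' @return Invisibly, `path`.
#' @export
write_cpg_table <- function(x, path, dialect = c("bismark_cov", "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  start <- if (dialect == "bismark_cov") x$pos + 1L else x$pos
  end <- if (dialect == "bismark_cov") x$pos + 1L else x$pos + 1L
  out <- data.frame(chrom = x$chrom, start = start, end = end,
                    pct = round(100 * x$meth / x$total, 6),
                    meth = x$meth, unmeth = x$total - x$meth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
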