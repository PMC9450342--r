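#' Merged genomic interval sets
#'
#' An `interval_set` is the package's counting footprint: per-contig
#' intervals in 0-based half-open coordinates, sorted, with overlapping or
#' book-ended intervals merged so that `total_bases()` equals the number of
#' distinct covered positions. Construction always merges, which makes
#' merging idempotent by design.
#'
#' @param contig character vector of canonical contig names.
#' @param start,end integer vectors, 0-based half-open (`end > start`).
#' @return an `interval_set`: data.frame with columns `contig`, `start`,
#'   `end`, rows sorted by contig rank then start.
#' @examples
#' iv <- interval_set(c("1", "1"), c(100, 150), c(200, 250))
#' total_bases(iv)
#' @export
interval_set <- function(contig = character(),
                         start = integer(),
                         end = integer()) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (length(contig) == 0) {
    df <- data.frame(contig = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
    return(structure(df, class = c("interval_set", "data.frame")))
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end <= start)) stop("interval end must exceed start")
  if (any(start < 0)) stop("negative interval start")
  # merge per contig; IRanges are 1-based closed, so [start,end) -> [start+1, end]
  # and book-ended half-open intervals become adjacent closed intervals, which
  # reduce() merges by default.
  pieces <- lapply(split(seq_along(contig), contig), function(i) {
    r <- IRanges::reduce(IRanges::IRanges(start = start[i] + 1L, end = end[i]))
    data.frame(contig = contig[i][1],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  df <- df[order(contig_rank(df$contig), df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"))
}

#' Total bases covered by an interval set
#'
#' Because interval sets are merged at construction, this equals the number
#' of distinct genomic positions covered.
#'
#' @param intervals an [interval_set()].
#' @return numeric count of covered bases.
#' @export
total_bases <- function(intervals) {
  stopifnot(inherits(intervals, "interval_set"))
  if (nrow(intervals) == 0) return(0)
  sum(as.numeric(intervals$end) - as.numeric(intervals$start))
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set:", nrow(x), "interval(s) on",
      length(unique(x$contig)), "contig(s),", total_bases(x), "bases\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# GRanges view of an interval_set (1-based closed), for overlap queries.
as_granges <- function(intervals) {
  stopifnot(inherits(intervals, "interval_set"))
  GenomicRanges::GRanges(
    seqnames = if (nrow(intervals)) intervals$contig else character(),
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

#' Write an interval set as BED
#'
#' Emits standard 6-column BED (0-based half-open) for inspection with
#' external tools. Output is deterministic.
#'
#' @param intervals an [interval_set()].
#' @param path output file path.
#' @param name feature name stem used in column 4.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path, name = "region") {
  stopifnot(inherits(intervals, "interval_set"))
  lines <- if (nrow(intervals) == 0) character() else {
    sprintf("%s\t%d\t%d\t%s_%d\t0\t+",
            intervals$contig, intervals$start, intervals$end,
            name, seq_len(nrow(intervals)))
  }
  writeLines(lines, path)
  invisible(path)
}
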