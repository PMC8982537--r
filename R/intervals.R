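# Genomic interval arithmetic.  All coordinates inside the package are
# 0-based half-open ([start, end)), the BED convention; 1-based sources must
# be converted at the reader boundary.  Strand is never consulted for
# enhancer or binding-site overlap; it is mandatory only for promoter
# windows, which are asymmetric around the TSS.

#' Validate interval coordinates
#'
#' Checks the half-open interval invariants: non-missing, `start >= 0`,
#' `end > start`.  Vectorised; the first offending row is named in the error.
#'
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param where Label used in error messages.
#' @return Invisibly `TRUE`; stops on violation.
#' @keywords internal
validate_intervals <- function(start, end, where = "interval") {
  if (length(start) != length(end))
    stop(where, ": start and end differ in length", call. = FALSE)
  if (anyNA(start) || anyNA(end))
    stop(where, ": missing coordinates", call. = FALSE)
  bad <- which(start < 0)
  if (length(bad))
    stop(where, ": negative start at row ", bad[1L], call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop(where, ": end <= start at row ", bad[1L], call. = FALSE)
  invisible(TRUE)
}

#' Normalize chromosome names
#'
#' Strips an optional `"chr"` prefix so that mixed naming conventions
#' (e.g. `chr1` vs `1`) compare equal.  Applied by all readers.
#'
#' @param chrom Character vector of chromosome names.
#' @param strip_prefix Strip a leading `"chr"`? Default `TRUE`.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, strip_prefix = TRUE) {
  if (strip_prefix) sub("^chr", "", as.character(chrom)) else as.character(chrom)
}

#' Test interval overlap
#'
#' Half-open overlap: two intervals overlap iff they share a chromosome and
#' `max(starts) < min(ends)`.  Book-ended intervals (`[0,10)` vs `[10,20)`)
#' do not overlap.  Strand is ignored.  Vectorised with recycling.
#'
#' @param chrom_a,start_a,end_a First interval set.
#' @param chrom_b,start_b,end_b Second interval set.
#' @return Logical vector.
#' @examples
#' iv_overlaps("chr1", 0, 10, "chr1", 9, 20)   # TRUE, one shared bp
#' iv_overlaps("chr1", 0, 10, "chr1", 10, 20)  # FALSE, adjacency
#' iv_overlaps("chr1", 0, 10, "chr2", 0, 10)   # FALSE, different chromosome
#' @export
iv_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  validate_intervals(start_a, end_a, "interval a")
  validate_intervals(start_b, end_b, "interval b")
  chrom_a == chrom_b & pmax(start_a, start_b) < pmin(end_a, end_b)
}

#' Interval center
#'
#' Midpoint of a half-open interval, `floor((start + end) / 2)`.  The floor
#' makes the center of an even-length interval deterministic in integer
#' arithmetic.  This is the anchor of the distal enhancer-target rule.
#'
#' @param start,end Interval coordinates (vectorised).
#' @return Integer vector of center positions, always inside `[start, end)`.
#' @export
interval_center <- function(start, end) {
  validate_intervals(start, end)
  (start + end) %/% 2
}

#' Strand-aware promoter window
#'
#' Builds the regulatory window around a TSS: on `+` it spans
#' `[tss - upstream, tss + downstream)`, on `-` the reflection
#' `[tss - downstream, tss + upstream)`.  The left edge is clipped at 0.
#' Defaults used by the pipeline: 10 kb / 1 kb for miRNA promoters and
#' 5 kb / 1 kb for gene promoters.
#'
#' @param tss Integer vector of 0-based TSS positions.
#' @param strand Character vector, each `"+"` or `"-"` (mandatory).
#' @param upstream,downstream Window extents in bp, non-negative scalars.
#' @return `data.frame` with columns `start`, `end`.
#' @export
promoter_window <- function(tss, strand, upstream, downstream) {
  if (length(upstream) != 1L || length(downstream) != 1L ||
      is.na(upstream) || is.na(downstream) || upstream < 0 || downstream < 0)
    stop("upstream and downstream must be non-negative scalars", call. = FALSE)
  if (anyNA(strand) || !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every TSS (promoter windows are asymmetric)",
         call. = FALSE)
  if (anyNA(tss) || any(tss < 0))
    stop("tss positions must be non-negative", call. = FALSE)
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  data.frame(start = pmax(0, start), end = end)
}

# All-pairs overlap join between two interval tables (columns chrom, start,
# end).  Returns data.frame(a_idx, b_idx).  Quadratic per chromosome, which
# is fine at the scales this package targets (thousands of features).
overlap_pairs <- function(a, b) {
  validate_intervals(a$start, a$end, "table a")
  validate_intervals(b$start, b$end, "table b")
  out_a <- integer(0)
  out_b <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    g <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
    keep <- pmax(a$start[g$i], b$start[g$j]) < pmin(a$end[g$i], b$end[g$j])
    out_a <- c(out_a, g$i[keep])
    out_b <- c(out_b, g$j[keep])
  }
  data.frame(a_idx = out_a, b_idx = out_b)
}

#' Merge intervals into disjoint coverage
#'
#' Unions overlapping or book-ended intervals per chromosome, yielding the
#' minimal sorted set of disjoint intervals with identical basepair
#' coverage.
#'
#' @param df `data.frame` with columns `chrom`, `start`, `end`.
#' @return `data.frame(chrom, start, end)`, sorted by (chrom, start).
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  validate_intervals(df$start, df$end, "merge_intervals")
  pieces <- lapply(split(df[c("chrom", "start", "end")], df$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    ms <- d$start[1L]
    me <- d$end[1L]
    starts <- integer(0)
    ends <- integer(0)
    if (nrow(d) > 1L) {
      for (i in 2:nrow(d)) {
        if (d$start[i] <= me) {
          me <- max(me, d$end[i])
        } else {
          starts <- c(starts, ms); ends <- c(ends, me)
          ms <- d$start[i]; me <- d$end[i]
        }
      }
    }
    data.frame(chrom = d$chrom[1L], start = c(starts, ms), end = c(ends, me))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Intersect two interval coverages
#'
#' Basepair-level intersection of two interval sets (each merged first).
#'
#' @param a,b `data.frame`s with columns `chrom`, `start`, `end`.
#' @return Merged `data.frame(chrom, start, end)` covering exactly the
#'   basepairs present in both inputs.
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  hits <- overlap_pairs(a, b)
  if (nrow(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  out <- data.frame(
    chrom = a$chrom[hits$a_idx],
    start = pmax(a$start[hits$a_idx], b$start[hits$b_idx]),
    end = pmin(a$end[hits$a_idx], b$end[hits$b_idx]))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
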