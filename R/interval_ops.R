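#' Interval set operations
#'
#' Overlap semantics follow BEDTools: two half-open intervals overlap when
#' they share at least one base pair; a shared boundary (end of one equals
#' start of the other) is not an overlap.
#'
#' * `overlap_intersect(a, b)` keeps the members of `a` that overlap any
#'   member of `b` (an asymmetric filter; `a` coordinates pass through
#'   unmodified).
#' * `subtract_overlapping(a, b)` keeps the members of `a` with no overlap in
#'   `b`. The two calls partition `a`.
#'
#' @param a,b `site_set` objects.
#' @return A `site_set` with `a`'s mark and label.
#' @export
overlap_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(new_site_set(a[0L], mark = site_mark(a), label = site_label(a)))
  hits <- findOverlaps(as_granges0(a), as_granges0(b))
  keep <- sort(unique(queryHits(hits)))
  new_site_set(a[keep], mark = site_mark(a), label = site_label(a))
}

#' @rdname overlap_intersect
#' @export
subtract_overlapping <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(new_site_set(copy(a), mark = site_mark(a), label = site_label(a)))
  hits <- findOverlaps(as_granges0(a), as_granges0(b))
  drop <- unique(queryHits(hits))
  keep <- setdiff(seq_len(nrow(a)), drop)
  new_site_set(a[keep], mark = site_mark(a), label = site_label(a))
}

#' Extend intervals by a flank and merge into maximal disjoint intervals
#'
#' Each interval is widened by `flank` bp on both sides (floored at 0), then
#' overlapping or book-ended intervals are merged (union of covered ranges on
#' the integer line). Used to turn point features such as CpG sites into
#' robust regions.
#'
#' @param points a `site_set`.
#' @param flank non-negative flank in bp.
#' @return A disjoint, sorted `site_set`.
#' @export
extend_and_merge <- function(points, flank = 0) {
  stopifnot(flank >= 0)
  if (nrow(points) == 0L)
    return(new_site_set(points[0L], mark = site_mark(points), label = site_label(points)))
  dt <- as.data.table(points)
  dt[, `:=`(start = pmax(start - flank, 0), end = end + flank)]
  gr <- reduce(GRanges(dt$chrom, IRanges(dt$start + 1, dt$end)))
  site_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
           mark = site_mark(points), label = site_label(points))
}

#' Resize intervals to a fixed width about their center
#'
#' Each interval is replaced by `[c - width/2, c + width/2)` where
#' `c = floor((start + end) / 2)`; the lower bound is clipped at 0 and, when
#' `chrom_sizes` is given, the upper bound at the chromosome length.
#'
#' @param sites a `site_set`.
#' @param width target width in bp (> 0).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A `site_set` of (near-)`width` intervals.
#' @export
resize_centered <- function(sites, width, chrom_sizes = NULL) {
  stopifnot(width > 0)
  if (nrow(sites) == 0L)
    return(new_site_set(sites[0L], mark = site_mark(sites), label = site_label(sites)))
  dt <- copy(as.data.table(sites))
  ctr <- (dt$start + dt$end) %/% 2
  half <- width %/% 2
  dt[, `:=`(start = pmax(ctr - half, 0), end = ctr - half + width)]
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[dt$chrom]
    dt[, end := pmin(end, lim)]
  }
  new_site_set(dt, mark = site_mark(sites), label = site_label(sites))
}
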