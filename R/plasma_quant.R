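#' Construct a plasma fragment set
#'
#' Holds the sequenced cfDNA fragments of one sample for one assay. Fragments
#' are BED-convention intervals; quantification collapses each fragment to the
#' 1-bp midpoint so a fragment can contribute to at most one site before
#' window resizing.
#'
#' @param chrom,start,end fragment coordinates (0-based half-open, length > 0).
#' @param sample_id sample identifier.
#' @param mark assay label (e.g. `"H3K4me3"`, `"H3K27ac"`).
#' @return A `fragment_set` object.
#' @export
fragment_set <- function(chrom, start, end, sample_id = NA_character_,
                         mark = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) > 0L && any(start < 0 | start >= end))
    stop("fragments must have 0 <= start < end")
  dt <- data.table(chrom = as.character(chrom), start = start, end = end)
  setattr(dt, "class", c("fragment_set", class(data.table())))
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "mark", mark)
  dt
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s  mark=%s  %d fragments\n",
              attr(x, "sample_id"), site_mark(x), nrow(x)))
  invisible(x)
}

#' Number of fragments in a fragment set
#' @param f a `fragment_set`.
#' @return Integer count.
#' @export
n_fragments <- function(f) nrow(f)

#' Read a per-sample fragment BED file
#'
#' @param path BED file of fragments (chrom, start, end), optionally gzipped.
#' @inheritParams fragment_set
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, sample_id = NA_character_, mark = NA_character_) {
  dt <- fread(path, header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"))
  fragment_set(dt$chrom, dt$start, dt$end, sample_id = sample_id, mark = mark)
}

#' Collapse fragments to 1-bp midpoints
#'
#' Each fragment is replaced by the 1-bp interval at `floor((start + end)/2)`.
#'
#' @param f a `fragment_set`.
#' @return A point `site_set` (all widths 1); duplicates are retained since
#'   distinct fragments may share a midpoint.
#' @export
midpoints <- function(f) {
  mid <- (f$start + f$end) %/% 2
  dt <- data.table(chrom = f$chrom, start = mid, end = mid + 1,
                   name = NA_character_, score = NA_real_)
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("site_set", class(data.table())))
  setattr(dt, "mark", site_mark(f))
  setattr(dt, "label", "midpoints")
  dt
}

#' Aggregate binned midpoint profile over a site set
#'
#' Every site is resized to a fixed `window` centered on the original site and
#' divided into `window / bin_width` bins; midpoints falling inside a resized
#' site are assigned to bin `floor((pos - site_start)/bin_width)` and counts
#' are summed across sites. A midpoint inside several (rarely overlapping)
#' resized windows counts once per window.
#'
#' @param sites nonempty `site_set` (original, un-resized coordinates).
#' @param pts point `site_set` of fragment midpoints (see [midpoints()]).
#' @param window aggregate window in bp (default 3000).
#' @param bin_width bin size in bp (default 40); must divide `window`.
#' @return An `aggregate_profile` with per-bin summed counts.
#' @export
aggregate_profile <- function(sites, pts, window = 3000, bin_width = 40) {
  stopifnot(window > 0, bin_width > 0)
  if (window %% bin_width != 0) stop("window must be divisible by bin_width")
  if (nrow(sites) == 0L) stop("empty site set")
  nbins <- window %/% bin_width
  resized <- resize_centered(sites, window)
  counts <- numeric(nbins)
  if (nrow(pts) > 0L) {
    ## per-chromosome IRanges overlap: midpoints are 1-bp points, a point in
    ## several overlapping resized windows counts once per window
    for (ch in unique(resized$chrom)) {
      rs <- resized[resized$chrom == ch]
      pos <- pts$start[pts$chrom == ch]
      if (length(pos) == 0L) next
      hits <- findOverlaps(IRanges(pos + 1, width = 1L),
                           IRanges(rs$start + 1, rs$end))
      if (length(hits) == 0L) next
      bin <- (pos[queryHits(hits)] - rs$start[subjectHits(hits)]) %/% bin_width
      counts <- counts + tabulate(bin + 1L, nbins = nbins)
    }
  }
  structure(list(site_set_label = site_label(sites), window = window,
                 bin_width = bin_width, bin_counts = as.numeric(counts),
                 shoulder_level = NULL, central_signal = NULL,
                 normalized_signal = NULL),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("<aggregate_profile> %s  %d bins x %d bp, total count %g\n",
              x$site_set_label, length(x$bin_counts), x$bin_width,
              sum(x$bin_counts)))
  if (!is.null(x$central_signal))
    cat(sprintf("  shoulder=%g  central=%g\n", x$shoulder_level, x$central_signal))
  invisible(x)
}

#' Shoulder (flank) background normalization of an aggregate profile
#'
#' The background level is estimated as the mean bin count over the outermost
#' `shoulder_frac` of bins on each side of the window; the central signal is
#' the sum, over the middle `central_frac` of bins, of the
#' background-subtracted counts floored at 0 per bin. An additive flat
#' background therefore cancels exactly.
#'
#' @param p an [aggregate_profile()].
#' @param shoulder_frac fraction of bins per side used as shoulder
#'   (default 0.2: bins 0-14 and 60-74 of a 75-bin window).
#' @param central_frac central fraction summed (default 1/3: the middle
#'   +/- 500 bp of a 3-kb window).
#' @return The profile with `shoulder_level` and `central_signal` filled in.
#' @export
shoulder_normalize <- function(p, shoulder_frac = 0.2, central_frac = 1/3) {
  stopifnot(inherits(p, "aggregate_profile"),
            shoulder_frac > 0, central_frac > 0)
  nb <- length(p$bin_counts)
  n_sh <- floor(nb * shoulder_frac)
  n_ce <- round(nb * central_frac)
  if (n_sh < 1L || n_ce < 1L) stop("window too small for shoulder geometry")
  sh_idx <- c(seq_len(n_sh), seq.int(nb - n_sh + 1L, nb))
  ce_lo <- floor((nb - n_ce) / 2) + 1L
  ce_idx <- seq.int(ce_lo, ce_lo + n_ce - 1L)
  if (length(intersect(sh_idx, ce_idx)) > 0L)
    stop("shoulder and central bin windows overlap; reduce fractions")
  p$shoulder_level <- mean(p$bin_counts[sh_idx])
  p$central_signal <- sum(pmax(p$bin_counts[ce_idx] - p$shoulder_level, 0))
  p
}

#' Housekeeping (DHS) reference signal of a sample
#'
#' The shoulder-normalized central signal of the sample's fragment midpoints
#' over a set of ubiquitously active DNase-hypersensitivity sites. Dividing
#' site signals by this reference removes sequencing-depth and global
#' efficiency differences between samples.
#'
#' @param sample a `fragment_set`.
#' @param dhs_sites nonempty `site_set` of housekeeping sites.
#' @inheritParams aggregate_profile
#' @inheritParams shoulder_normalize
#' @return Positive scalar reference signal.
#' @section Errors: a sample whose reference signal is not positive (e.g. zero
#'   fragments) raises a condition of class `cfties_unquantifiable`.
#' @export
dhs_reference <- function(sample, dhs_sites, window = 3000, bin_width = 40,
                          shoulder_frac = 0.2, central_frac = 1/3) {
  stopifnot(nrow(dhs_sites) > 0L)
  pts <- midpoints(sample)
  p <- shoulder_normalize(aggregate_profile(dhs_sites, pts, window, bin_width),
                          shoulder_frac, central_frac)
  if (!is.finite(p$central_signal) || p$central_signal <= 0)
    stop(structure(class = c("cfties_unquantifiable", "error", "condition"),
                   list(message = paste0("sample ", attr(sample, "sample_id"),
                                         ": housekeeping reference signal is not positive; ",
                                         "sample unquantifiable"),
                        call = sys.call(-1))))
  p$central_signal
}

#' Depth-normalized signal of a sample over a site set
#'
#' Shoulder-normalized central signal over `sites` divided by the sample's
#' housekeeping reference ([dhs_reference()]); scale-free with respect to
#' sequencing depth.
#'
#' @inheritParams dhs_reference
#' @param sites nonempty `site_set` to quantify.
#' @return Nonnegative scalar signal.
#' @export
site_signal <- function(sample, sites, dhs_sites, window = 3000, bin_width = 40,
                        shoulder_frac = 0.2, central_frac = 1/3) {
  ref <- dhs_reference(sample, dhs_sites, window, bin_width,
                       shoulder_frac, central_frac)
  pts <- midpoints(sample)
  p <- shoulder_normalize(aggregate_profile(sites, pts, window, bin_width),
                          shoulder_frac, central_frac)
  p$central_signal / ref
}
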