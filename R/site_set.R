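#' @importFrom data.table data.table as.data.table setorder := fread fwrite rbindlist copy setDF setDT
#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct a genomic site set
#'
#' A `site_set` is the unit of every signature in the package: an ordered,
#' duplicate-free collection of genomic intervals in BED convention (0-based,
#' half-open) tagged with an assay mark and a provenance label. All interval
#' operations ([overlap_intersect()], [extend_and_merge()], ...) take and
#' return `site_set` objects.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` (BED half-open).
#' @param name optional per-site labels.
#' @param score optional per-site numeric scores.
#' @param mark assay label, one of `"H3K4me3"`, `"H3K27ac"`, `"MeDIP"`,
#'   `"TFBS"`, `"DHS"`, or `NA`.
#' @param label free-text provenance string (e.g. `"tRCC-up"`).
#'
#' @details Sites are sorted by (chrom, start, end); exact duplicate
#'   (chrom, start, end) triples are dropped and zero-length records rejected.
#' @return A `site_set` (data.table with columns chrom/start/end/name/score
#'   and `mark`/`label` attributes).
#' @export
site_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NA_character_, score = NA_real_,
                     mark = NA_character_, label = NA_character_) {
  n <- length(start)
  stopifnot(length(end) == n)
  chrom <- rep_len(as.character(chrom), n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0L) {
    bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
    if (length(bad) > 0L)
      stop("invalid interval(s) at position(s) ", paste(utils::head(bad, 5L), collapse = ", "),
           ": need 0 <= start < end")
  }
  dt <- data.table(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n))
  setorder(dt, chrom, start, end)
  dt <- unique(dt, by = c("chrom", "start", "end"))
  new_site_set(dt, mark = mark, label = label)
}

new_site_set <- function(dt, mark = NA_character_, label = NA_character_) {
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  dt <- as.data.table(dt)
  if (!"name" %in% names(dt)) dt[, name := NA_character_]
  if (!"score" %in% names(dt)) dt[, score := NA_real_]
  dt <- dt[, c("chrom", "start", "end", "name", "score"), with = FALSE]
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("site_set", class(data.table())))
  setattr(dt, "mark", mark)
  setattr(dt, "label", label)
  dt
}

setattr <- function(x, name, value) data.table::setattr(x, name, value)

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> %d sites  mark=%s  label=%s\n",
              nrow(x), site_mark(x), site_label(x)))
  if (nrow(x) > 0L) print(as.data.table(utils::head(as.data.frame(x), 6L)))
  invisible(x)
}

#' Mark and label accessors for site sets and fragment sets
#' @param x a `site_set` or `fragment_set`.
#' @return Character scalar.
#' @export
site_mark <- function(x) attr(x, "mark", exact = TRUE)

#' @rdname site_mark
#' @export
site_label <- function(x) attr(x, "label", exact = TRUE)

## 1-based closed GRanges view used for overlap queries only; BED arithmetic
## stays on the 0-based half-open columns.
as_granges0 <- function(x) {
  if (nrow(x) == 0L)
    return(GRanges())
  GRanges(x$chrom, IRanges(start = x$start + 1, end = x$end))
}

#' Read a BED3/BED6 file into a site set
#'
#' Lines beginning with `track`, `browser` or `#` are skipped; columns beyond
#' the sixth are ignored. Coordinates must be non-negative integers with
#' `start < end`; a malformed line raises an error naming its line number.
#'
#' @param path path to a (possibly gzipped) BED file.
#' @inheritParams site_set
#' @return A sorted, deduplicated [site_set()].
#' @export
read_bed <- function(path, mark = NA_character_, label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(site_set(mark = mark, label = label))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", idx[which(nf < 3L)[1L]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s_raw <- vapply(fields, `[[`, "", 2L)
  e_raw <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  e <- suppressWarnings(as.numeric(e_raw))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e) | s < 0 | s >= e)
  if (length(bad) > 0L)
    stop("line ", idx[bad[1L]], ": malformed BED coordinates '",
         s_raw[bad[1L]], " ", e_raw[bad[1L]], "'")
  nm <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  sc <- suppressWarnings(as.numeric(ifelse(nf >= 5L,
          vapply(fields, function(f) f[min(5L, length(f))], ""), NA_character_)))
  site_set(chrom, s, e, name = nm, score = sc, mark = mark, label = label)
}

#' Write a site set or fragment set as BED
#'
#' @param x a `site_set` or `fragment_set`.
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  dt <- as.data.table(x)[, c("chrom", "start", "end"), with = FALSE]
  if ("name" %in% names(x) && any(!is.na(x$name))) dt[, name := x$name]
  fwrite(dt, path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path tab-separated file with columns name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "length"))
  stats::setNames(as.numeric(dt$length), dt$chrom)
}
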