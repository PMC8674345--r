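## Peak-set data model and interval algebra.
##
## A peak set is a GRanges with metadata columns `name` (character) and
## `score` (non-negative numeric, the peak intensity), sorted by
## (chrom, start, end) and free of duplicate (chrom, start, end) triples.
## Files use BED 0-based half-open coordinates; GRanges are 1-based closed.

#' Construct a peak set from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (BED convention);
#'   `start < end` is required.
#' @param name peak identifiers (recycled; default `"."`).
#' @param score numeric peak intensities (recycled; default `0`).
#' @param strand strand characters (`"+"`, `"-"` or `"."`; default `"."`).
#' @param sort sort and deduplicate the result (default `TRUE`).
#' @return A `GRanges` peak set.
#' @export
peak_set <- function(chrom, start, end, name = ".", score = 0,
                     strand = ".", sort = TRUE) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character(0)
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid interval at position %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1], format(start[bad[1]]), format(end[bad[1]])))
  }
  strand <- ifelse(strand %in% c("+", "-"), strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$name <- rep_len(as.character(name), length(gr))
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), length(gr))
  if (sort) gr <- sort_and_validate(gr) else gr
}

#' Sort and validate a peak set
#'
#' Sorts by (chrom, start, end) and removes duplicated
#' (chrom, start, end) triples, keeping the first occurrence.
#'
#' @param peaks a `GRanges` peak set.
#' @param report if `TRUE`, message the number of duplicates removed.
#' @return Sorted, deduplicated `GRanges`; the number of removed duplicates
#'   is attached as attribute `"n_duplicates_removed"`.
#' @export
sort_and_validate <- function(peaks, report = FALSE) {
  stopifnot(is(peaks, "GRanges"))
  GenomeInfoDb::seqlevels(peaks) <- sort(GenomeInfoDb::seqlevels(peaks))
  o <- order(as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaks <- peaks[o]
  key <- paste(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  dup <- duplicated(key)
  ndup <- sum(dup)
  if (ndup > 0) peaks <- peaks[!dup]
  if (report && ndup > 0)
    message(sprintf("removed %d duplicate interval(s)", ndup))
  attr(peaks, "n_duplicates_removed") <- ndup
  peaks
}

#' Read a BED file as a peak set
#'
#' Accepts 3 to 6 columns; missing name/score/strand are filled with
#' `"."`, `0` and `"."`. Lines beginning with `#`, `track` or `browser`
#' are skipped. Malformed coordinates are reported with their line number.
#'
#' @param path path to a BED file (plain text, tab or space separated).
#' @return Sorted, validated `GRanges` peak set.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) return(peak_set(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: line %d has %d field(s); at least 3 required",
                 path, lineno[which(nf < 3L)[1]], nf[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s: malformed coordinates at line %d (start=%s, end=%s)",
                 path, lineno[bad[1]],
                 vapply(fields, `[`, "", 2L)[bad[1]],
                 vapply(fields, `[`, "", 3L)[bad[1]]))
  getcol <- function(i, default) {
    v <- vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
    v[is.na(v)] <- default
    v
  }
  name <- getcol(4L, ".")
  score <- suppressWarnings(as.numeric(getcol(5L, "0")))
  score[is.na(score)] <- 0
  strand <- getcol(6L, ".")
  peak_set(chrom, start, end, name = name, score = score, strand = strand)
}

#' Write a peak set as BED6
#'
#' Coordinates are emitted 0-based half-open; the score column is the peak
#' intensity times 1000, rounded to integer.
#'
#' @param peaks `GRanges` peak set.
#' @param path output path.
#' @param score_scale multiplier applied to `score` before rounding
#'   (default 1000).
#' @export
write_bed <- function(peaks, path, score_scale = 1000) {
  st <- as.character(GenomicRanges::strand(peaks))
  st[st == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = S4Vectors::mcols(peaks)$name,
    score = as.integer(round(S4Vectors::mcols(peaks)$score * score_scale)),
    strand = st
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## put two GRanges on a shared seqlevel set so findOverlaps never warns
## about disjoint sequence universes
.shared_levels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Partition two peak sets by overlap
#'
#' Splits each set into the peaks that overlap the other set by at least
#' one base (common) and those that do not (unique). Overlap is
#' strand-blind, and a peak overlapping several partners is counted once
#' (peak-anchored counting).
#'
#' @param a,b `GRanges` peak sets (validated; see [sort_and_validate()]).
#' @return A list of class `"OverlapPartition"` with elements `a_unique`,
#'   `a_common`, `b_unique`, `b_common` (all `GRanges`) and `pair_index`, a
#'   data.frame mapping indices of common A peaks to overlapping B peaks.
#' @export
intersect_partition <- function(a, b) {
  h <- .shared_levels(a, b)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = TRUE)
  ai <- unique(S4Vectors::queryHits(hits))
  bi <- unique(S4Vectors::subjectHits(hits))
  out <- list(
    a_unique = if (length(a)) a[setdiff(seq_along(a), ai)] else a,
    a_common = a[ai],
    b_unique = if (length(b)) b[setdiff(seq_along(b), bi)] else b,
    b_common = b[bi],
    pair_index = data.frame(a_index = S4Vectors::queryHits(hits),
                            b_index = S4Vectors::subjectHits(hits))
  )
  class(out) <- c("OverlapPartition", "list")
  out
}

#' Classify peak dynamics between two conditions
#'
#' @param vehicle,treated `GRanges` peak sets for the two conditions.
#' @return A list of class `"DynamicsPartition"`: `lost` (vehicle peaks with
#'   no treated overlap), `shared` (vehicle peaks overlapping treated),
#'   `gained` (treated peaks with no vehicle overlap) and `shared_treated`
#'   (treated peaks overlapping vehicle).
#' @export
classify_dynamics <- function(vehicle, treated) {
  pv <- intersect_partition(vehicle, treated)
  out <- list(
    lost = pv$a_unique,
    shared = pv$a_common,
    gained = pv$b_unique,
    shared_treated = pv$b_common
  )
  class(out) <- c("DynamicsPartition", "list")
  out
}

#' Merge intervals separated by at most a gap
#'
#' Intervals whose gap (next start minus previous end, 0-based) is less
#' than or equal to `max_gap` are unioned transitively; constituent scores
#' are summed and constituent counts recorded.
#'
#' @param peaks `GRanges` peak set.
#' @param max_gap maximum allowed gap in bases (>= 0).
#' @return `GRanges` of merged regions with metadata columns `name`,
#'   `score` (sum of constituent scores) and `n_constituents`.
#' @export
merge_intervals <- function(peaks, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (length(peaks) == 0L) {
    S4Vectors::mcols(peaks)$n_constituents <- integer(0)
    return(peaks)
  }
  red <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1,
                               with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  score <- vapply(revmap, function(i) sum(S4Vectors::mcols(peaks)$score[i]), 0)
  n <- lengths(revmap)
  out <- GenomicRanges::granges(red)
  S4Vectors::mcols(out)$name <- sprintf("region_%d", seq_along(out))
  S4Vectors::mcols(out)$score <- score
  S4Vectors::mcols(out)$n_constituents <- n
  S4Vectors::mcols(out)$revmap <- revmap
  out
}
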