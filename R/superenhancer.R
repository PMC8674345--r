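## Super-enhancer calling: stitch enhancer peaks, rank stitched regions by
## total signal, and cut the ranked (hockey-stick) curve at the point where
## the unit-scaled tangent has slope 1. Regions above the cutoff signal are
## super-enhancers.

#' Stitch enhancer peaks into regions
#'
#' Peaks separated by at most `stitch_distance` bases are merged
#' transitively. When a TSS table is supplied, peaks lying fully within
#' `tss_exclusion` bases of any TSS are removed before stitching
#' (promoter-proximal filtering); by default no exclusion is applied.
#'
#' @param peaks `GRanges` peak set.
#' @param stitch_distance maximum gap in bases (default 12500).
#' @param tss_table optional gene table; `NULL` disables TSS exclusion.
#' @param tss_exclusion half-width in bases of the exclusion zone around
#'   each TSS (default 2500).
#' @return `GRanges` of stitched regions with `score` (sum of constituent
#'   peak scores) and `n_constituents`.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss_table = NULL,
                         tss_exclusion = 2500) {
  stopifnot(stitch_distance >= 0)
  if (!is.null(tss_table) && length(peaks)) {
    excl <- GenomicRanges::GRanges(
      seqnames = tss_table$chrom,
      ranges = IRanges::IRanges(start = pmax(tss_table$tss - tss_exclusion + 1, 1),
                                end = tss_table$tss + tss_exclusion)
    )
    h <- .shared_levels(peaks, excl)
    inside <- GenomicRanges::countOverlaps(h$a, h$b, type = "within",
                                           ignore.strand = TRUE) > 0
    peaks <- peaks[!inside]
  }
  merge_intervals(peaks, max_gap = stitch_distance)
}

#' Rank stitched regions and flag super-enhancers
#'
#' Regions are ranked by increasing total signal and placed on a unit
#' square (x = rank / n, y = signal / max signal). The cutoff is the point
#' where the scaled curve's tangent has slope 1, found as the minimum of
#' (y - x); regions with signal strictly above the cutoff signal are
#' flagged as super-enhancers.
#'
#' @param stitched `GRanges` of stitched regions (>= 2). Total signal is
#'   taken from `mcols(stitched)$total_signal` if present, otherwise from
#'   `score`, unless a `track` is supplied.
#' @param track optional `SignalTrack`; when given, total signal is the sum
#'   of track values over each region.
#' @return List of class `"SERanking"`: `regions` (`GRanges` in ascending
#'   signal order with `total_signal`, `rank`, `scaled_x`, `scaled_y`,
#'   `is_super`), `cutoff_signal`, `cutoff_rank` and `n_super`.
#' @export
rank_enhancers <- function(stitched, track = NULL) {
  if (length(stitched) < 2) stop("need at least 2 stitched regions")
  sig <- if (!is.null(track)) {
    quantify_regions(stitched, track, statistic = "sum")
  } else if (!is.null(S4Vectors::mcols(stitched)$total_signal)) {
    S4Vectors::mcols(stitched)$total_signal
  } else {
    S4Vectors::mcols(stitched)$score
  }
  if (is.null(sig)) stop("no signal available: supply a track or total_signal")
  o <- order(sig, as.character(GenomicRanges::seqnames(stitched)),
             GenomicRanges::start(stitched))
  regions <- stitched[o]
  sig <- sig[o]
  n <- length(sig)
  x <- seq_len(n) / n
  maxsig <- max(sig)
  if (maxsig <= 0 || min(sig) == maxsig) {
    warning("all region signals are equal; scaled curve lies on the diagonal, no super-enhancers called")
    y <- if (maxsig > 0) sig / maxsig else rep(0, n)
    cutoff_rank <- n
    cutoff_signal <- sig[n]
  } else {
    y <- sig / maxsig
    cutoff_rank <- which.min(y - x)
    cutoff_signal <- sig[cutoff_rank]
  }
  is_super <- sig > cutoff_signal
  S4Vectors::mcols(regions)$total_signal <- sig
  S4Vectors::mcols(regions)$rank <- seq_len(n)
  S4Vectors::mcols(regions)$scaled_x <- x
  S4Vectors::mcols(regions)$scaled_y <- y
  S4Vectors::mcols(regions)$is_super <- is_super
  structure(list(regions = regions, cutoff_signal = cutoff_signal,
                 cutoff_rank = cutoff_rank, n_super = sum(is_super)),
            class = c("SERanking", "list"))
}

#' @export
print.SERanking <- function(x, ...) {
  cat(sprintf("SERanking: %d regions, %d super-enhancers (cutoff signal %.4g)\n",
              length(x$regions), x$n_super, x$cutoff_signal))
  invisible(x)
}

#' Per-region signal fold change between two tracks
#'
#' @param se an `SERanking` or a `GRanges` of regions.
#' @param track_a,track_b `SignalTrack`s (e.g. vehicle and treated).
#' @param pseudocount positive value added to both sums (default 1).
#' @return data.frame with `name`, `chrom`, `start`, `end` (0-based
#'   half-open), `signal_a`, `signal_b`, `log2fc` =
#'   log2((signal_b + pseudocount) / (signal_a + pseudocount)).
#' @export
se_fold_change <- function(se, track_a, track_b, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  regions <- if (is(se, "SERanking") || (is.list(se) && !is.null(se$regions)))
    se$regions else se
  chroms <- as.character(GenomicRanges::seqnames(regions))
  lens <- track_lengths(track_a)
  outside <- !(chroms %in% names(lens)) |
    GenomicRanges::start(regions) > lens[chroms]
  if (any(outside, na.rm = TRUE))
    warning(sum(outside, na.rm = TRUE),
            " region(s) outside the track extent treated as zero signal")
  sa <- quantify_regions(regions, track_a, statistic = "sum")
  sb <- quantify_regions(regions, track_b, statistic = "sum")
  data.frame(
    name = S4Vectors::mcols(regions)$name,
    chrom = chroms,
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    signal_a = sa, signal_b = sb,
    log2fc = log2((sb + pseudocount) / (sa + pseudocount)),
    stringsAsFactors = FALSE
  )
}
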