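## Piecewise-constant genome-wide signal tracks (bedGraph) and
## peak-centered pileup profiling.
##
## A SignalTrack stores one numeric Rle per chromosome; position i of the
## Rle is the value at 0-based base i-1. Bases not covered by any bedGraph
## run read as 0. Chromosome lengths bound the track: queries beyond a
## chromosome end are truncation, queries inside it but beyond the last
## run read 0.

#' Construct a signal track from runs
#'
#' @param runs data.frame-like with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `value`; runs on a chromosome must not overlap.
#' @param chrom_lengths optional named vector of chromosome lengths in
#'   bases; defaults to the largest run end per chromosome.
#' @param resolution informational resolution note in bases (default `NA`).
#' @return An object of class `"SignalTrack"`.
#' @export
signal_track <- function(runs, chrom_lengths = NULL, resolution = NA_real_) {
  runs <- as.data.frame(runs)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(runs)))
  if (nrow(runs) && any(!is.finite(runs$value)))
    stop("signal values must be finite")
  if (nrow(runs) && any(runs$start < 0 | runs$start >= runs$end))
    stop("runs must satisfy 0 <= start < end")
  chroms <- sort(unique(c(as.character(runs$chrom), names(chrom_lengths))))
  cov <- list()
  for (ch in chroms) {
    r <- runs[runs$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping runs on ", ch)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      as.numeric(chrom_lengths[[ch]]) else if (nrow(r)) max(r$end) else 0
    if (nrow(r) && max(r$end) > len)
      stop("run beyond declared chromosome length on ", ch)
    if (nrow(r) == 0L) {
      cov[[ch]] <- S4Vectors::Rle(0, len)
      next
    }
    # interleave zero gaps with run values
    gap_before <- r$start - c(0, r$end[-nrow(r)])
    vals <- as.vector(rbind(0, r$value))
    lens <- as.vector(rbind(gap_before, r$end - r$start))
    tailgap <- len - r$end[nrow(r)]
    if (tailgap > 0) { vals <- c(vals, 0); lens <- c(lens, tailgap) }
    keep <- lens > 0
    cov[[ch]] <- S4Vectors::Rle(vals[keep], lens[keep])
  }
  structure(list(cov = cov, resolution = resolution), class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d chromosome(s), %s bases total\n",
              length(x$cov), format(sum(track_lengths(x)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a signal track
#' @param track a `SignalTrack`.
#' @return Named numeric vector of per-chromosome lengths.
#' @export
track_lengths <- function(track) {
  vapply(track$cov, length, 0)
}

#' Read a 4-column bedGraph file
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param chrom_lengths optional named chromosome lengths.
#' @return A `SignalTrack`. Overlapping runs or non-numeric values are
#'   rejected with the offending line number.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 4L)
    stop(path, ": expected 4 columns, found ", ncol(dt))
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  dt[, line := .I]
  if (!is.numeric(dt$start) || !is.numeric(dt$end) || !is.numeric(dt$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$value))))[1]
    stop(sprintf("%s: non-numeric field at line %d", path,
                 if (is.na(bad)) 1L else bad))
  }
  bad <- dt[start < 0 | start >= end, line]
  if (length(bad))
    stop(sprintf("%s: invalid run coordinates at line %d", path, bad[1]))
  data.table::setorder(dt, chrom, start)
  ov <- dt[, .(bad = line[-1][start[-1] < end[-.N]]), by = chrom]$bad
  if (length(ov))
    stop(sprintf("%s: overlapping runs at line %d", path, ov[1]))
  signal_track(dt[, .(chrom, start, end, value)], chrom_lengths = chrom_lengths)
}

#' Write a signal track as bedGraph
#'
#' Zero-valued runs are omitted (uncovered bases read as 0 on re-import).
#'
#' @param track a `SignalTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    # %.17g guarantees the double round-trips through text exactly
    data.table::data.table(chrom = ch, start = starts[keep],
                           end = ends[keep],
                           value = sprintf("%.17g", vals[keep]))
  })
  dt <- data.table::rbindlist(pieces)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## value vector over 0-based half-open [from, to) on one chromosome;
## out-of-chromosome positions are NA (truncation), positions beyond the
## last run but inside the chromosome are 0.
.track_window <- function(track, chrom, from, to) {
  n <- to - from
  r <- track$cov[[chrom]]
  if (is.null(r)) return(rep(NA_real_, n))
  len <- length(r)
  lo <- max(from, 0); hi <- min(to, len)
  out <- rep(NA_real_, n)
  if (hi > lo)
    out[(lo - from + 1):(hi - from)] <- as.numeric(r[(lo + 1):hi])
  out
}

#' Binned signal pileup around peak centers
#'
#' For each peak, bins of `bin_width` bases tile the half-open window
#' `[center - flank, center + flank)` left to right, where the center is
#' `floor((start + end) / 2)` in 0-based coordinates. Each bin value is the
#' mean track value over the bin's bases. Windows truncated by a chromosome
#' end use only the in-chromosome bases and flag the row.
#'
#' @param peaks `GRanges` peak set.
#' @param track a `SignalTrack`.
#' @param flank half-window in bases (default 2000).
#' @param bin_width bin size in bases (default 50); must divide `2*flank`.
#' @return A numeric matrix (peaks x bins) of class `"ProfileMatrix"` with
#'   attributes `flank`, `bin_width` and `truncated` (logical per row).
#' @export
profile_matrix <- function(peaks, track, flank = 2000, bin_width = 50) {
  stopifnot(flank > 0, bin_width > 0)
  if ((2 * flank) %% bin_width != 0)
    stop("bin_width must divide 2*flank")
  nbins <- as.integer(2 * flank / bin_width)
  centers <- floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  mat <- matrix(NA_real_, nrow = length(peaks), ncol = nbins)
  truncated <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    v <- .track_window(track, chroms[i], centers[i] - flank, centers[i] + flank)
    truncated[i] <- anyNA(v)
    dim(v) <- c(bin_width, nbins)
    mat[i, ] <- colMeans(v, na.rm = TRUE)
  }
  mat[is.nan(mat)] <- NA_real_
  rownames(mat) <- S4Vectors::mcols(peaks)$name
  structure(mat, flank = flank, bin_width = bin_width, truncated = truncated,
            class = c("ProfileMatrix", "matrix", "array"))
}

#' Average pileup profile
#'
#' Column means of a profile matrix, excluding truncated rows.
#'
#' @param matrix a `ProfileMatrix` from [profile_matrix()].
#' @return Numeric vector of per-bin means.
#' @export
mean_profile <- function(matrix) {
  truncated <- attr(matrix, "truncated")
  keep <- !truncated
  if (!any(keep)) stop("all profile rows are truncated")
  colMeans(matrix[keep, , drop = FALSE])
}

#' Quantify track signal over regions
#'
#' @param regions `GRanges` regions.
#' @param track a `SignalTrack`.
#' @param statistic `"mean"` or `"sum"` over the region's in-chromosome
#'   bases; a region with no covered bases yields 0.
#' @return Numeric vector, one value per region.
#' @export
quantify_regions <- function(regions, track, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  lens <- track_lengths(track)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    r <- track$cov[[ch]]
    if (is.null(r)) { out[idx] <- 0; next }
    len <- length(r)
    s <- pmax(GenomicRanges::start(regions)[idx], 1L)
    e <- pmin(GenomicRanges::end(regions)[idx], len)
    ok <- which(s <= e)
    if (length(ok)) {
      vw <- IRanges::Views(r, start = s[ok], end = e[ok])
      sums <- IRanges::viewSums(vw)
      out[idx[ok]] <- if (statistic == "sum") sums else sums / (e[ok] - s[ok] + 1)
    }
  }
  out
}
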