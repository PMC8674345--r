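# Brute-force oracles and fixture builders shared across the suite.
# Oracles work on plain data.frames with 0-based half-open coordinates and
# never call the interval machinery they are checking.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# random peak set; returns both the data.frame (0-based) and the GRanges
rand_peak_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                         max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("p%d", seq_len(n)),
             score = round(runif(n, 0, 10), 3),
             stringsAsFactors = FALSE)
}

df_to_peaks <- function(df) {
  peak_set(df$chrom, df$start, df$end, name = df$name, score = df$score)
}

peaks_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), name = mcols(gr)$name, score = mcols(gr)$score,
             stringsAsFactors = FALSE)
}

# O(n^2) all-pairs overlap on 0-based half-open intervals
bf_overlapping_rows <- function(a_df, b_df) {
  hit <- logical(nrow(a_df))
  for (i in seq_len(nrow(a_df))) {
    hit[i] <- any(b_df$chrom == a_df$chrom[i] &
                    b_df$start < a_df$end[i] &
                    b_df$end > a_df$start[i])
  }
  hit
}

# transitive-closure merge by label propagation (gap <= max_gap links)
bf_merge_components <- function(df, max_gap) {
  n <- nrow(df)
  comp <- seq_len(n)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    df$chrom[i] == df$chrom[j] &
      (pmax(df$start[i], df$start[j]) - pmin(df$end[i], df$end[j])) <= max_gap
  })
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

# dense per-base signal vector (0-based index i stored at position i + 1)
bf_dense_track <- function(runs, len) {
  v <- numeric(len)
  for (i in seq_len(nrow(runs)))
    v[(runs$start[i] + 1):runs$end[i]] <- runs$value[i]
  v
}

# per-base bin-averaging oracle for one peak center (0-based)
bf_profile_row <- function(dense, center, flank, bin_width) {
  nbins <- 2 * flank / bin_width
  out <- numeric(nbins)
  for (b in seq_len(nbins)) {
    lo <- center - flank + (b - 1) * bin_width  # 0-based inclusive
    hi <- lo + bin_width - 1
    pos <- lo:hi
    pos <- pos[pos >= 0 & pos < length(dense)]
    out[b] <- if (length(pos)) mean(dense[pos + 1]) else NA_real_
  }
  out
}

# small but class-rich simulation used by several tests
tiny_sim_config <- function(seed = 3, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 3e6, n_genes = 60,
             n_peaks_a = 150, n_peaks_b = 120, signature_size = 3,
             n_samples = 4, ...)
}
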