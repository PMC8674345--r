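## TSS-window annotation, gene occupancy classes, resampling enrichment
## and hypergeometric gene-set overlap.
##
## A gene table is a data.frame with columns `gene_id` (unique), `chrom`,
## `tss` (0-based base) and `strand` ("+"/"-"). Windows around the TSS are
## half-open: a peak is in the window iff it overlaps [tss - w, tss + w).

#' Construct a gene table
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param tss 0-based TSS coordinates (>= 0).
#' @param strand `"+"` or `"-"`.
#' @return data.frame gene table.
#' @export
gene_table <- function(gene_id, chrom, tss, strand = "+") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (length(tss) && any(tss < 0)) stop("tss must be >= 0")
  data.frame(gene_id = gene_id, chrom = as.character(chrom),
             tss = as.numeric(tss),
             strand = rep_len(as.character(strand), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Read a TSV gene table
#' @param path tab-separated file with header `gene_id, chrom, tss, strand`.
#' @return data.frame gene table.
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(dt)))
    stop(path, ": gene table must have columns ", paste(req, collapse = ", "))
  gene_table(dt$gene_id, dt$chrom, dt$tss, dt$strand)
}

## 1-based GRanges for half-open windows [tss - w, tss + w)
.tss_windows <- function(genes, window_kb) {
  w <- window_kb * 1000
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(genes$tss - w + 1, 1),
                              end = genes$tss + w)
  )
}

#' Assign peaks to genes by TSS proximity
#'
#' A peak is assigned to gene `g` when it overlaps the half-open window
#' `[tss - w, tss + w)` with `w = window_kb * 1000` bases (strand-blind).
#'
#' @param peaks `GRanges` peak set.
#' @param genes gene table (see [gene_table()]).
#' @param window_kb window half-width in kilobases (> 0).
#' @return data.frame with columns `gene_id`, `peak_index`, `peak_name`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window_kb) {
  stopifnot(window_kb > 0)
  win <- .tss_windows(genes, window_kb)
  h <- .shared_levels(win, peaks)
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = TRUE)
  data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    peak_index = S4Vectors::subjectHits(hits),
    peak_name = S4Vectors::mcols(peaks)$name[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}

## logical: does each gene have >= 1 peak in its window?
.gene_bound <- function(peaks, genes, window_kb) {
  win <- .tss_windows(genes, window_kb)
  h <- .shared_levels(win, peaks)
  GenomicRanges::countOverlaps(h$a, h$b, ignore.strand = TRUE) > 0
}

#' Four-class gene occupancy by two peak sets
#'
#' Classifies each gene by which factors have at least one peak within the
#' TSS window: `common` (both), `A_only`, `B_only`, or `none`.
#'
#' @param genes gene table.
#' @param peaks_a,peaks_b `GRanges` peak sets for factors A and B.
#' @param window_kb window half-width in kilobases (default 10).
#' @return data.frame with columns `gene_id` and `class` (factor with
#'   levels `A_only`, `B_only`, `common`, `none`).
#' @export
occupancy_classes <- function(genes, peaks_a, peaks_b, window_kb = 10) {
  stopifnot(window_kb > 0)
  a <- .gene_bound(peaks_a, genes, window_kb)
  b <- .gene_bound(peaks_b, genes, window_kb)
  cls <- ifelse(a & b, "common", ifelse(a, "A_only", ifelse(b, "B_only", "none")))
  data.frame(gene_id = genes$gene_id,
             class = factor(cls, levels = c("A_only", "B_only", "common", "none")),
             stringsAsFactors = FALSE)
}

#' Resampling enrichment of peak proximity in a gene set
#'
#' Computes the percentage of query genes with at least one peak within
#' `window_kb` of the TSS, compares it with `n_iter` equal-size random
#' gene sets drawn without replacement from the universe, and reports the
#' odds ratio (observed percentage over mean null percentage), a
#' +1-corrected empirical p-value and a one-sided one-sample t-test of the
#' null percentages against the observed value.
#'
#' @param query_genes character vector of gene ids (subset of the universe).
#' @param peaks `GRanges` peak set.
#' @param universe gene table defining the sampling universe.
#' @param window_kb TSS window half-width in kilobases (default 20).
#' @param n_iter number of random draws (default 1000).
#' @param seed integer seed for the null draws.
#' @return List of class `"EnrichmentResult"`: `observed_pct`, `null_pcts`,
#'   `odds_ratio`, `p_empirical`, `p_t`, `n_query`, `seed`.
#' @export
resample_enrichment <- function(query_genes, peaks, universe, window_kb = 20,
                                n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 1)
  query_genes <- unique(as.character(query_genes))
  if (!all(query_genes %in% universe$gene_id))
    stop("query_genes must be a subset of the universe gene ids")
  k <- length(query_genes)
  n_univ <- nrow(universe)
  if (k > n_univ) stop("query larger than universe")
  if (k == 0L) stop("empty query gene set")
  bound <- .gene_bound(peaks, universe, window_kb)
  names(bound) <- universe$gene_id
  observed_pct <- 100 * mean(bound[query_genes])
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  null_pcts <- vapply(seq_len(n_iter), function(i) {
    100 * mean(bound[sample.int(n_univ, k)])
  }, 0)
  null_mean <- mean(null_pcts)
  if (null_mean == 0) {
    if (observed_pct == 0) {
      warning("no gene in the universe has a proximal peak; odds ratio set to 0")
      odds_ratio <- 0
    } else {
      warning("all null percentages are zero; odds ratio reported as Inf")
      odds_ratio <- Inf
    }
  } else {
    odds_ratio <- observed_pct / null_mean
  }
  p_empirical <- (1 + sum(null_pcts >= observed_pct)) / (n_iter + 1)
  p_t <- if (stats::sd(null_pcts) == 0) {
    if (null_mean < observed_pct) 0 else 1
  } else {
    stats::t.test(null_pcts, mu = observed_pct, alternative = "less")$p.value
  }
  structure(list(observed_pct = observed_pct, null_pcts = null_pcts,
                 odds_ratio = odds_ratio, p_empirical = p_empirical,
                 p_t = p_t, n_query = k, seed = as.integer(seed)),
            class = c("EnrichmentResult", "list"))
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(paste0("EnrichmentResult: observed %.2f%% vs null mean %.2f%% ",
                     "(OR = %.3g, empirical p = %.3g, t-test p = %.3g, n = %d)\n"),
              x$observed_pct, mean(x$null_pcts), x$odds_ratio,
              x$p_empirical, x$p_t, x$n_query))
  invisible(x)
}

#' Hypergeometric upper-tail overlap test
#'
#' Probability of observing `k` or more shared genes between a set of size
#' `K` and a set of size `n` drawn from a universe of `N` genes.
#'
#' @param k observed overlap count.
#' @param K size of the first gene set.
#' @param n size of the second gene set.
#' @param N universe size (must be passed explicitly).
#' @return Upper-tail probability `P(X >= k)`.
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
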