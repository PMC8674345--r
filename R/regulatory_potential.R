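## Regulatory-potential scoring and binding-association curves.
##
## Each gene is scored by a distance-decayed sum over nearby peaks,
## rp = sum over peaks with |center - tss| <= L of exp(-(a + b*Delta)),
## Delta = |center - tss| / L, with the classical decay constants a = 0.5,
## b = 4 and half-window L = 100 kb. A peak at the TSS contributes
## exp(-0.5) ~ 0.607; a peak at the window edge exp(-4.5) ~ 0.011.

#' Regulatory-potential scores
#'
#' @param genes gene table (see [gene_table()]).
#' @param peaks `GRanges` peak set; the peak position is the interval
#'   midpoint `floor((start + end) / 2)` in 0-based coordinates.
#' @param half_window decay half-window in bases (default 1e5); peaks with
#'   centers farther than this from the TSS contribute nothing.
#' @param decay_offset,decay_slope the decay constants a and b
#'   (defaults 0.5 and 4).
#' @return data.frame with columns `gene_id`, `rp_score`,
#'   `n_peaks_in_window`.
#' @export
regulatory_potential <- function(genes, peaks, half_window = 1e5,
                                 decay_offset = 0.5, decay_slope = 4) {
  stopifnot(half_window > 0)
  centers <- floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2)
  chrom_p <- as.character(GenomicRanges::seqnames(peaks))
  rp <- numeric(nrow(genes))
  npk <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    cc <- sort(centers[chrom_p == ch])
    if (length(cc) == 0L) next
    for (j in gi) {
      lo <- findInterval(genes$tss[j] - half_window - 0.5, cc) + 1L
      hi <- findInterval(genes$tss[j] + half_window + 0.5, cc)
      if (hi >= lo) {
        d <- abs(cc[lo:hi] - genes$tss[j])
        rp[j] <- sum(exp(-(decay_offset + decay_slope * d / half_window)))
        npk[j] <- hi - lo + 1L
      }
    }
  }
  data.frame(gene_id = genes$gene_id, rp_score = rp,
             n_peaks_in_window = npk, stringsAsFactors = FALSE)
}

#' Binding-association curves for regulated gene classes
#'
#' Ranks all scored genes by decreasing regulatory potential (ties broken
#' by `gene_id`), builds the cumulative-fraction curve of each gene class
#' along that ranking, and tests up- and down-regulated classes against the
#' static background with a one-sided two-sample Kolmogorov-Smirnov test on
#' the rank positions (alternative: the regulated class sits at better,
#' i.e. smaller, ranks).
#'
#' @param rp data.frame from [regulatory_potential()].
#' @param up_genes,down_genes,static_genes character vectors of gene ids;
#'   the classes must be disjoint and `static_genes` non-empty.
#' @return List of class `"AssociationResult"`: `ranking` (gene_id in rank
#'   order), `curves` (list of per-class cumulative-fraction vectors over
#'   rank) and `tests` (data.frame with class, ks_statistic, p_value).
#' @export
beta_association <- function(rp, up_genes, down_genes, static_genes) {
  classes <- list(upregulated = unique(as.character(up_genes)),
                  downregulated = unique(as.character(down_genes)),
                  static = unique(as.character(static_genes)))
  if (length(classes$static) == 0L) stop("static gene class must be non-empty")
  allq <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(allq)) stop("gene classes must be disjoint")
  missing <- setdiff(allq, rp$gene_id)
  if (length(missing))
    stop("genes absent from the rp table: ", paste(head(missing, 3), collapse = ", "))
  ord <- order(-rp$rp_score, rp$gene_id)
  ranking <- rp$gene_id[ord]
  n <- length(ranking)
  rank_of <- seq_len(n)
  names(rank_of) <- ranking
  curves <- lapply(classes, function(g) {
    if (length(g) == 0L) return(numeric(n))
    cumsum(tabulate(rank_of[g], nbins = n)) / length(g)
  })
  tests <- list()
  for (cl in c("upregulated", "downregulated")) {
    if (length(classes[[cl]]) == 0L) {
      warning("empty ", cl, " class; comparison skipped")
      next
    }
    kt <- suppressWarnings(
      stats::ks.test(rank_of[classes[[cl]]], rank_of[classes$static],
                     alternative = "greater")
    )
    tests[[cl]] <- data.frame(class = cl,
                              ks_statistic = unname(kt$statistic),
                              p_value = kt$p.value,
                              stringsAsFactors = FALSE)
  }
  structure(list(ranking = ranking, curves = curves,
                 tests = do.call(rbind, tests)),
            class = c("AssociationResult", "list"))
}
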