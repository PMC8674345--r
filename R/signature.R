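## Gene-signature scoring and the small statistical comparisons used for
## class-wise expression contrasts.

#' Per-sample signature z-scores
#'
#' For each gene, z = (x - mu) / sigma across samples, with mu the study
#' mean and sigma the sample (n - 1) standard deviation; a sample's
#' signature score is the sum of z over the signature genes present in the
#' matrix. Genes with zero variance are dropped with a warning; signature
#' genes absent from the matrix are skipped.
#'
#' @param expr numeric matrix (genes x samples) with gene ids as row names
#'   and sample ids as column names; at least 2 samples.
#' @param signature character vector of gene ids.
#' @return data.frame with `sample_id`, `score`, `n_genes_used`. Scores sum
#'   to zero across samples by construction.
#' @export
signature_zscore <- function(expr, signature) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples for z-scoring")
  if (is.null(colnames(expr)))
    colnames(expr) <- sprintf("sample_%d", seq_len(ncol(expr)))
  if (any(!is.finite(expr))) stop("expression values must be finite")
  present <- intersect(unique(as.character(signature)), rownames(expr))
  if (length(present) == 0L) stop("no signature gene present in the matrix")
  sub <- expr[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sigma <- apply(sub, 1, stats::sd)
  zerovar <- sigma == 0
  if (any(zerovar)) {
    warning(sum(zerovar), " signature gene(s) with zero variance dropped")
    sub <- sub[!zerovar, , drop = FALSE]
    mu <- mu[!zerovar]; sigma <- sigma[!zerovar]
  }
  if (nrow(sub) == 0L) stop("all signature genes have zero variance")
  z <- (sub - mu) / sigma
  data.frame(
    sample_id = colnames(expr),
    score = colSums(z),
    n_genes_used = nrow(sub),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pairwise rank-sum comparison of labeled value groups
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of classes, with
#' Benjamini-Hochberg adjustment across the pairs. Classes with fewer than
#' 3 values are skipped with a warning.
#'
#' @param values_by_class named list of numeric vectors.
#' @return data.frame with `class1`, `class2`, `n1`, `n2`, `statistic`,
#'   `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(values_by_class) {
  stopifnot(is.list(values_by_class), length(values_by_class) >= 2,
            !is.null(names(values_by_class)))
  sizes <- lengths(values_by_class)
  small <- names(values_by_class)[sizes < 3]
  if (length(small))
    warning("class(es) with fewer than 3 values skipped: ",
            paste(small, collapse = ", "))
  keep <- names(values_by_class)[sizes >= 3]
  if (length(keep) < 2) stop("fewer than 2 classes with >= 3 values")
  pairs <- utils::combn(keep, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    c1 <- pairs[1, i]; c2 <- pairs[2, i]
    wt <- suppressWarnings(
      stats::wilcox.test(values_by_class[[c1]], values_by_class[[c2]],
                         alternative = "two.sided")
    )
    data.frame(class1 = c1, class2 = c2,
               n1 = length(values_by_class[[c1]]),
               n2 = length(values_by_class[[c2]]),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Chi-squared comparison of two up/down count ratios
#'
#' 2x2 chi-squared test without continuity correction on the counts of
#' up- and down-regulated genes in two conditions.
#'
#' @param up1,down1 counts in condition 1.
#' @param up2,down2 counts in condition 2.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
ratio_chisq <- function(up1, down1, up2, down2) {
  counts <- c(up1, down1, up2, down2)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every margin of the 2x2 table must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}
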