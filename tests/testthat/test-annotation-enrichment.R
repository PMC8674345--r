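# TSS-window annotation, occupancy classes, resampling enrichment and
# hypergeometric overlap.

test_that("assign_peaks_to_genes respects the half-open window", {
  g <- gene_table("g1", "chr1", 50000, "+")
  w <- 10  # kb
  # peak exactly at the TSS
  expect_equal(nrow(assign_peaks_to_genes(peak_set("chr1", 50000, 50100),
                                          g, w)), 1L)
  # peak starting exactly at tss + w is outside the half-open window
  expect_equal(nrow(assign_peaks_to_genes(peak_set("chr1", 60000, 60100),
                                          g, w)), 0L)
  # peak ending at tss - w + 1 still overlaps by one base
  expect_equal(nrow(assign_peaks_to_genes(peak_set("chr1", 39000, 40001),
                                          g, w)), 1L)
  expect_equal(nrow(assign_peaks_to_genes(peak_set("chr1", 39000, 40000),
                                          g, w)), 0L)
})

test_that("assign_peaks_to_genes matches the all-pairs distance oracle", {
  set.seed(7)
  genes <- gene_table(sprintf("g%d", 1:300), sample(c("chr1", "chr2"), 300, TRUE),
                      sample.int(2e5, 300), "+")
  pdf <- rand_peak_df(300, max_pos = 2e5)
  peaks <- df_to_peaks(pdf)
  got <- assign_peaks_to_genes(peaks, genes, window_kb = 5)
  sdf <- peaks_to_df(peaks)
  w <- 5000
  expected <- 0L
  for (i in seq_len(nrow(genes))) {
    lo <- genes$tss[i] - w; hi <- genes$tss[i] + w
    n_i <- sum(sdf$chrom == genes$chrom[i] & sdf$start < hi & sdf$end > lo)
    expected <- expected + n_i
    expect_equal(sum(got$gene_id == genes$gene_id[i]), n_i)
  }
  expect_equal(nrow(got), expected)
})

test_that("occupancy_classes partitions genes by window co-occupancy", {
  g <- gene_table(c("g1", "g2"), "chr1", c(50000, 200000), c("+", "-"))
  none <- occupancy_classes(g, peak_set(character(0), integer(0), integer(0)),
                            peak_set(character(0), integer(0), integer(0)))
  expect_true(all(none$class == "none"))

  a <- peak_set("chr1", 45000 - 100, 45000)        # tss - 5000 region
  b <- peak_set("chr1", 59999, 60050)              # last base of the window
  oc <- occupancy_classes(g, a, b, window_kb = 10)
  expect_equal(as.character(oc$class), c("common", "none"))
  expect_equal(nrow(oc), nrow(g))
  expect_equal(sum(table(oc$class)), nrow(g))
})

test_that("occupancy classes on synthetic data match a brute-force oracle", {
  ds <- simulate_dataset(tiny_sim_config(seed = 9))
  adf <- peaks_to_df(ds$peaks$a_vehicle)
  bdf <- peaks_to_df(ds$peaks$b_vehicle)
  w <- ds$config$tss_window_kb * 1000
  for (i in seq_len(nrow(ds$genes))) {
    lo <- ds$genes$tss[i] - w; hi <- ds$genes$tss[i] + w
    a <- any(adf$chrom == ds$genes$chrom[i] & adf$start < hi & adf$end > lo)
    b <- any(bdf$chrom == ds$genes$chrom[i] & bdf$start < hi & bdf$end > lo)
    want <- if (a && b) "common" else if (a) "A_only" else if (b) "B_only" else "none"
    expect_equal(as.character(ds$classes$class[i]), want)
  }
})

test_that("resample_enrichment degenerate and identity cases", {
  genes <- gene_table(sprintf("g%d", 1:50), "chr1",
                      seq(10000, by = 50000, length.out = 50), "+")
  peaks <- peak_set("chr1", genes$tss[1:10] - 50, genes$tss[1:10] + 50)
  # query = universe: every draw is the universe, OR = 1 exactly
  e <- resample_enrichment(genes$gene_id, peaks, genes, window_kb = 1,
                           n_iter = 50, seed = 1)
  expect_equal(e$odds_ratio, 1)
  expect_equal(length(e$null_pcts), 50L)
  expect_true(all(e$null_pcts == e$observed_pct))
  # no bound gene anywhere: OR defined as 0 with a warning
  far <- peak_set("chr2", 0, 100)
  expect_warning(
    e0 <- resample_enrichment(genes$gene_id[1:5], far, genes, window_kb = 1,
                              n_iter = 20, seed = 1),
    "odds ratio")
  expect_equal(e0$odds_ratio, 0)
  expect_equal(e0$observed_pct, 0)
  expect_error(resample_enrichment("nope", peaks, genes, n_iter = 5, seed = 1),
               "subset")
})

test_that("resample_enrichment recovers a planted 5-fold enrichment", {
  # universe of 1000 genes, 200 bound; query = 100 genes, all bound
  genes <- gene_table(sprintf("g%04d", 1:1000), "chr1",
                      seq(5e4, by = 5e4, length.out = 1000), "+")
  bound_idx <- 1:200
  peaks <- peak_set("chr1", genes$tss[bound_idx] - 100,
                    genes$tss[bound_idx] + 100,
                    name = sprintf("pk%d", bound_idx))
  e <- resample_enrichment(genes$gene_id[1:100], peaks, genes,
                           window_kb = 20, n_iter = 1000, seed = 42)
  # analytic null: mean 20%, SE of the null mean ~ 1.26%/sqrt(1000)
  se_null <- sd(e$null_pcts)
  expect_equal(e$observed_pct, 100)
  expect_lt(abs(e$odds_ratio - 5), 3 * se_null * 5 / 20)
  expect_lt(e$p_empirical, 0.01)
  expect_lt(e$p_t, 1e-10)
  # deterministic under the seed
  e2 <- resample_enrichment(genes$gene_id[1:100], peaks, genes,
                            window_kb = 20, n_iter = 1000, seed = 42)
  expect_identical(e$null_pcts, e2$null_pcts)
})

test_that("enrichment OR is invariant to relabeling and permutation", {
  set.seed(3)
  genes <- gene_table(sprintf("g%d", 1:200), sample(c("chr1", "chr2"), 200, TRUE),
                      sample.int(1e6, 200), "+")
  pdf <- rand_peak_df(100, max_pos = 1e6)
  peaks <- df_to_peaks(pdf)
  q <- sample(genes$gene_id, 40)
  e1 <- resample_enrichment(q, peaks, genes, window_kb = 10, n_iter = 200, seed = 5)
  # permute the universe table: same OR because draws index the same genes
  perm <- sample(nrow(genes))
  # relabel chromosomes consistently in genes and peaks
  relab <- function(x) ifelse(x == "chr1", "chrA", "chrB")
  genes2 <- gene_table(genes$gene_id[perm], relab(genes$chrom[perm]),
                       genes$tss[perm], "+")
  pdf2 <- pdf; pdf2$chrom <- relab(pdf2$chrom)
  e2 <- resample_enrichment(q, df_to_peaks(pdf2), genes2, window_kb = 10,
                            n_iter = 200, seed = 5)
  expect_equal(e2$observed_pct, e1$observed_pct)
  # null distribution differs only through the permuted index draw; the
  # analytic target (mean null) is unchanged in expectation, and the OR
  # must agree to within resampling error
  expect_equal(e2$odds_ratio, e1$odds_ratio, tolerance = 0.15)
})

test_that("hypergeom_overlap matches exhaustive enumeration and summation", {
  expect_equal(hypergeom_overlap(0, 5, 5, 10), 1)
  expect_equal(hypergeom_overlap(5, 5, 5, 10), 1 / choose(10, 5))
  # exhaustive enumeration for all small universes
  for (N in 2:12) {
    for (n in 1:(N - 1)) {
      draws <- utils::combn(N, n)          # all C(N, n) gene-set draws
      for (K in 1:(N - 1)) {
        overlap <- colSums(draws <= K)     # genes 1..K form the first set
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_overlap(k, K, n, N),
                       mean(overlap >= k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeom_overlap large-count case matches direct summation", {
  # log-space direct summation oracle
  direct <- function(k, K, n, N) {
    kk <- k:min(K, n)
    sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
  }
  p <- hypergeom_overlap(49, 593, 241, 1000)
  expect_equal(p, direct(49, 593, 241, 1000), tolerance = 1e-12)
  expect_error(hypergeom_overlap(10, 5, 5, 10), "inconsistent")
})
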