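# Synthetic-data generator: planted ground truth, determinism, file I/O.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(co_binding_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(treated_intensity_scale = 0), "\\(0, 1\\]")
  expect_error(sim_config(n_peaks_a = 10, n_peaks_b = 100,
                          co_binding_fraction = 0.5), "distinct A partner")
  expect_error(sim_config(n_chroms = 0), "positive")
})

test_that("simulate_genome: empty, deterministic, spacing honoured", {
  cfg0 <- tiny_sim_config()
  cfg0$n_genes <- 0L
  expect_equal(nrow(simulate_genome(cfg0)), 0L)

  cfg <- tiny_sim_config(seed = 12)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), cfg$n_genes)
  # minimum spacing of 2x the +/-10 kb annotation window span
  spacing <- 4 * cfg$tss_window_kb * 1000
  for (ch in unique(g1$chrom))
    expect_true(all(diff(g1$tss[g1$chrom == ch]) >= spacing))
  # infeasible request names the spacing constraint
  expect_error(simulate_genome(sim_config(n_chroms = 1, chrom_length = 1e6,
                                          n_genes = 500)),
               "spacing")
})

test_that("per-chromosome gene counts replay exactly from the seed", {
  cfg <- tiny_sim_config(seed = 77)
  g <- simulate_genome(cfg)
  counts <- table(g$chrom)
  # independent re-draw with the recorded generator recipe
  redraw <- cistromics:::.with_stream(cfg$seed, "genome", {
    as.vector(stats::rmultinom(1, cfg$n_genes, rep(0.5, 2)))
  })
  expect_equal(as.vector(counts), redraw)
})

test_that("cistromes plant the exact co-binding fraction", {
  # rho = 0: no common B peaks
  cfg0 <- tiny_sim_config(co_binding_fraction = 0)
  cis0 <- simulate_cistromes(cfg0)
  p0 <- intersect_partition(cis0$a_vehicle, cis0$b_vehicle)
  expect_equal(length(p0$b_common), 0L)
  # rho = 1 on a small B set: all common
  cfg1 <- tiny_sim_config(co_binding_fraction = 1)
  cfg1$n_peaks_b <- 10L
  cis1 <- simulate_cistromes(cfg1)
  p1 <- intersect_partition(cis1$a_vehicle, cis1$b_vehicle)
  expect_equal(length(p1$b_common), 10L)
  # rho = 0.25: count exact, verified via the interval-overlap machinery
  cfg <- tiny_sim_config(seed = 5)
  cis <- simulate_cistromes(cfg)
  p <- intersect_partition(cis$a_vehicle, cis$b_vehicle)
  expect_equal(length(p$b_common), round(0.25 * cfg$n_peaks_b))
  expect_equal(sort(mcols(p$b_common)$name), sort(cis$truth$common_b))
  # realized fraction is exact by construction
  expect_equal(length(p$b_common) / cfg$n_peaks_b,
               round(cfg$co_binding_fraction * cfg$n_peaks_b) / cfg$n_peaks_b)
})

test_that("treatment dynamics and intensity scaling are planted exactly", {
  cfg <- tiny_sim_config(seed = 8)
  cis <- simulate_cistromes(cfg)
  dyn <- classify_dynamics(cis$b_vehicle, cis$b_treated)
  expect_equal(length(dyn$lost), round(cfg$loss_fraction * cfg$n_peaks_b))
  expect_equal(length(dyn$gained), round(cfg$gain_fraction * cfg$n_peaks_b))
  expect_equal(sort(mcols(dyn$shared)$name), sort(cis$truth$shared_b))
  expect_equal(sort(mcols(dyn$gained)$name), sort(cis$truth$gained))
  # mean treated / vehicle intensity over shared peaks = delta exactly
  veh <- mcols(cis$b_vehicle)
  trt <- mcols(cis$b_treated)
  shared <- intersect(veh$name, trt$name)
  ratio <- mean(trt$score[match(shared, trt$name)]) /
    mean(veh$score[match(shared, veh$name)])
  expect_equal(ratio, cfg$treated_intensity_scale, tolerance = 1e-12)
})

test_that("simulated tracks follow the Gaussian-bump closed form", {
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 1e5, n_genes = 0,
                    n_peaks_a = 1, n_peaks_b = 1, signature_size = 0,
                    signal_background = 1)
  # no peaks: constant background
  t0 <- cistromics:::.bumps_track(peak_set(character(0), integer(0),
                                           integer(0)), cfg)
  expect_equal(runValue(t0$cov$chr1), 1)
  expect_equal(length(t0$cov$chr1), 1e5)
  # single peak, center on the evaluation grid
  p <- peak_set("chr1", 50000 - 200, 50000 + 200, score = 10)
  tr <- cistromics:::.bumps_track(p, cfg)
  v <- as.numeric(tr$cov$chr1)
  expect_equal(v[50001], 11, tolerance = 1e-4)              # background + a
  expect_equal(v[50101], 1 + 10 * exp(-0.5), tolerance = 1e-4)
  expect_equal(v[50000 - 100 + 1], 1 + 10 * exp(-0.5), tolerance = 1e-4)
})

test_that("expression couples to binding class with planted effects", {
  ds <- simulate_dataset(tiny_sim_config(seed = 9))
  cfg <- ds$config
  fc <- ds$expression$fc
  expect_equal(fc$planted_effect[fc$class == "A_only"],
               rep(cfg$expr_effect_a, sum(fc$class == "A_only")))
  expect_equal(fc$planted_effect[fc$class == "B_only"],
               rep(-cfg$expr_effect_b, sum(fc$class == "B_only")))
  expect_equal(fc$planted_effect[fc$class == "none"],
               rep(0, sum(fc$class == "none")))
  # noiseless generator reproduces the planted effects exactly
  cfg0 <- tiny_sim_config(seed = 9, expr_noise_sd = 0)
  ds0 <- simulate_dataset(cfg0)
  expect_identical(ds0$expression$fc$log2fc, ds0$expression$fc$planted_effect)
  # and with zero effects everything is exactly zero
  cfgz <- tiny_sim_config(seed = 9, expr_noise_sd = 0, expr_effect_a = 0,
                          expr_effect_b = 0)
  expect_true(all(simulate_dataset(cfgz)$expression$fc$log2fc == 0))
  # B-only class mean sits within 3 analytic SE of -effect_b
  nb <- sum(fc$class == "B_only")
  expect_lt(abs(mean(fc$log2fc[fc$class == "B_only"]) + cfg$expr_effect_b),
            3 * cfg$expr_noise_sd / sqrt(nb))
  # signature genes are B-only and the list is deterministic
  expect_true(all(ds$expression$signature %in%
                    fc$gene_id[fc$class == "B_only"]))
  cfg_big_sig <- tiny_sim_config(seed = 9)
  cfg_big_sig$signature_size <- 1e5
  expect_error(simulate_dataset(cfg_big_sig), "exceeds the number")
})

test_that("write_dataset round-trips and replays byte-identically", {
  cfg <- tiny_sim_config(seed = 4)
  ds <- simulate_dataset(cfg)
  td <- tempfile()
  write_dataset(ds, td)
  ds2 <- read_dataset(td)
  # coordinates and names identical; scores quantized to 1/1000
  for (nm in names(ds$peaks)[1:4]) {
    expect_identical(granges(ds2$peaks[[nm]]), granges(ds$peaks[[nm]]))
    expect_identical(mcols(ds2$peaks[[nm]])$name, mcols(ds$peaks[[nm]])$name)
    expect_lt(max(abs(mcols(ds2$peaks[[nm]])$score -
                        mcols(ds$peaks[[nm]])$score)), 5e-4 + 1e-12)
  }
  for (nm in names(ds$tracks)) {
    for (ch in names(ds$tracks[[nm]]$cov)) {
      expect_identical(runValue(ds2$tracks[[nm]]$cov[[ch]]),
                       runValue(ds$tracks[[nm]]$cov[[ch]]))
      expect_identical(runLength(ds2$tracks[[nm]]$cov[[ch]]),
                       runLength(ds$tracks[[nm]]$cov[[ch]]))
    }
  }
  expect_equal(ds2$genes, ds$genes)
  expect_equal(ds2$expression$fc$log2fc, ds$expression$fc$log2fc)
  expect_identical(ds2$signature, ds$expression$signature)
  # written BED records are sorted and validate cleanly
  for (nm in names(ds$peaks)[1:4]) {
    p <- read_bed(file.path(td, "peaks", paste0(nm, ".bed")))
    expect_equal(attr(sort_and_validate(p), "n_duplicates_removed"), 0L)
  }
  # manifest seed replay: regenerate and compare digests
  td2 <- tempfile()
  write_dataset(simulate_dataset(cfg), td2)
  m1 <- jsonlite::read_json(file.path(td, "manifest.json"), simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(td2, "manifest.json"), simplifyVector = TRUE)
  expect_identical(m1$files, m2$files)
  expect_equal(m1$seed, cfg$seed)
})
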