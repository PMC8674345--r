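## Seeded synthetic-data generator with planted ground truth.
##
## The generator emulates the data regime of a two-factor cistrome study:
## factor A (an androgen-receptor-like factor, treatment-stable) and
## factor B (a MYC-like factor whose binding collapses under treatment),
## an acetylation-like signal track concentrated at peaks, and expression
## fold changes coupled to each gene's binding class. Every stochastic
## stage consumes a named RNG substream derived from the master seed, so
## identical (config, seed) reproduce byte-identical files.

#' Simulation configuration
#'
#' Defaults define the study conditions: 4 chromosomes x 30 Mb, 1000
#' genes, 2400 peaks per factor with a co-binding fraction of 0.25, a
#' treatment that removes 59% of B peaks and adds 14% new low-intensity
#' ones while halving the intensity of persisting B peaks
#' (`treated_intensity_scale = 0.5`), Gaussian signal bumps of amplitude
#' ~N(10, 2) over background 0.1, planted log2 expression effects of +1
#' for A-bound genes and -1 for B-only genes with noise SD 0.2, 6 samples
#' and a 136-gene signature.
#'
#' @param seed master integer seed.
#' @param n_chroms,chrom_length number and length (bases) of chromosomes.
#' @param n_genes number of genes.
#' @param n_peaks_a,n_peaks_b peaks per factor.
#' @param co_binding_fraction fraction of B peaks placed overlapping a
#'   distinct A peak (exact by construction).
#' @param peak_width_log_mean,peak_width_log_sd log-normal peak width
#'   parameters (widths floored at `min_peak_width`).
#' @param loss_fraction,gain_fraction fraction of B peaks lost under
#'   treatment, and number of new treated peaks as a fraction of
#'   `n_peaks_b`.
#' @param treated_intensity_scale multiplier in (0, 1] applied to the
#'   intensity of persisting B peaks under treatment.
#' @param signal_background,signal_amplitude_mean,signal_amplitude_sd
#'   track background value per base and bump amplitude distribution.
#' @param expr_effect_a,expr_effect_b planted log2 fold-change effects for
#'   A-bound and B-only genes.
#' @param expr_noise_sd log2 noise SD for fold changes and samples.
#' @param n_samples columns of the per-sample expression matrix.
#' @param signature_size number of B-only genes in the signature list.
#' @param track_resolution bedGraph run resolution in bases (default 10).
#' @param min_peak_width floor on simulated peak widths (default 100).
#' @param edge_margin peak centers and TSSs are kept this far from
#'   chromosome ends so profile windows never truncate (default 5000).
#' @param tss_window_kb annotation window half-width in kb used for the
#'   planted occupancy classes; TSS spacing is 4x this (default 10).
#' @return Validated list of class `"SimConfig"`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4, chrom_length = 3e7,
                       n_genes = 1000,
                       n_peaks_a = 2400, n_peaks_b = 2400,
                       co_binding_fraction = 0.25,
                       peak_width_log_mean = log(400),
                       peak_width_log_sd = 0.25,
                       loss_fraction = 0.59, gain_fraction = 0.14,
                       treated_intensity_scale = 0.5,
                       signal_background = 0.1,
                       signal_amplitude_mean = 10,
                       signal_amplitude_sd = 2,
                       expr_effect_a = 1, expr_effect_b = 1,
                       expr_noise_sd = 0.2,
                       n_samples = 6, signature_size = 136,
                       track_resolution = 10, min_peak_width = 100,
                       edge_margin = 5000, tss_window_kb = 10) {
  cfg <- as.list(environment())
  props <- c("co_binding_fraction", "loss_fraction", "gain_fraction")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (treated_intensity_scale <= 0 || treated_intensity_scale > 1)
    stop("treated_intensity_scale must be in (0, 1]")
  pos <- c("n_chroms", "chrom_length", "n_peaks_a", "n_peaks_b",
           "n_samples", "track_resolution", "min_peak_width",
           "tss_window_kb")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be positive")
  if (n_genes < 0 || signature_size < 0 || edge_margin < 0)
    stop("counts must be non-negative")
  if (expr_noise_sd < 0 || signal_background < 0)
    stop("noise and background must be non-negative")
  if (round(co_binding_fraction * n_peaks_b) > n_peaks_a)
    stop("co_binding_fraction * n_peaks_b exceeds n_peaks_a: each co-bound ",
         "B peak needs a distinct A partner")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("SimConfig", "list"))
}

.chrom_names <- function(config) sprintf("chr%d", seq_len(config$n_chroms))

#' Simulate the gene annotation
#'
#' Places `n_genes` TSSs uniformly per chromosome with a minimum spacing
#' of twice the span of the annotation window (4 x `tss_window_kb`), so
#' occupancy classes are unambiguous; strands are random.
#'
#' @param config a [sim_config()].
#' @return Gene table ordered by (chrom, tss).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_genes == 0L)
    return(gene_table(character(0), character(0), numeric(0), character(0)))
  spacing <- 4 * config$tss_window_kb * 1000
  chroms <- .chrom_names(config)
  usable <- config$chrom_length - 2 * config$edge_margin
  placed <- .with_stream(config$seed, "genome", {
    counts <- as.vector(stats::rmultinom(1, config$n_genes,
                                         rep(1 / config$n_chroms,
                                             config$n_chroms)))
    slack <- usable - (counts - 1) * spacing
    if (any(slack <= 0))
      stop("TSS spacing infeasible: ", counts[which(slack <= 0)[1]],
           " genes on a ", config$chrom_length, " bp chromosome cannot keep ",
           "the minimum spacing of ", spacing,
           " bp (2x the +/-", config$tss_window_kb,
           " kb annotation window); reduce n_genes or enlarge chromosomes")
    tss_list <- lapply(seq_along(chroms), function(i) {
      u <- sort(stats::runif(counts[i], 0, slack[i]))
      round(config$edge_margin + u + (seq_len(counts[i]) - 1) * spacing)
    })
    list(counts = counts, tss = tss_list)
  })
  chrom <- rep(chroms, placed$counts)
  tss <- unlist(placed$tss)
  strand <- .with_stream(config$seed, "strands",
                         sample(c("+", "-"), config$n_genes, replace = TRUE))
  ids <- sprintf("G%0*d", nchar(as.character(config$n_genes)),
                 seq_len(config$n_genes))
  gene_table(ids, chrom, tss, strand)
}

## place n peaks with given widths, centers uniform per chromosome
## (length-proportional chromosome choice), avoiding any overlap with
## `avoid` and among themselves; rejection sampling with a round budget.
.place_peaks <- function(n, widths, config, avoid, stream, seed) {
  chroms <- .chrom_names(config)
  if (n == 0L)
    return(GenomicRanges::GRanges())
  .with_stream(seed, stream, {
    accepted <- GenomicRanges::GRanges()
    remaining <- seq_len(n)
    out_chrom <- character(n); out_start <- numeric(n)
    for (round in seq_len(100L)) {
      m <- length(remaining)
      ch <- chroms[sample.int(config$n_chroms, m, replace = TRUE)]
      w <- widths[remaining]
      ctr <- round(stats::runif(m, config$edge_margin,
                                config$chrom_length - config$edge_margin))
      start1 <- pmax(ctr - floor(w / 2) + 1, 1)  # 1-based
      prop <- GenomicRanges::GRanges(factor(ch, levels = chroms),
                                     IRanges::IRanges(start1, width = w))
      ok <- rep(TRUE, m)
      if (length(avoid)) {
        h <- .shared_levels(prop, avoid)
        ok <- GenomicRanges::countOverlaps(h$a, h$b, ignore.strand = TRUE) == 0
      }
      if (length(accepted)) {
        h <- .shared_levels(prop, accepted)
        ok <- ok & GenomicRanges::countOverlaps(h$a, h$b,
                                                ignore.strand = TRUE) == 0
      }
      # self-collisions within the round: keep the lower-index proposal
      self <- GenomicRanges::findOverlaps(prop, prop, ignore.strand = TRUE)
      self <- self[S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)]
      clash <- S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)
      ok[unique(S4Vectors::queryHits(self)[clash])] <- FALSE
      take <- which(ok)
      if (length(take)) {
        idx <- remaining[take]
        out_chrom[idx] <- ch[take]
        out_start[idx] <- GenomicRanges::start(prop)[take]
        accepted <- c(accepted, prop[take])
        remaining <- remaining[-take]
      }
      if (length(remaining) == 0L) break
    }
    if (length(remaining))
      stop("peak placement collision budget exhausted for ",
           length(remaining), " peak(s); consider longer chromosomes")
    GenomicRanges::GRanges(out_chrom,
                           IRanges::IRanges(out_start, width = widths))
  })
}

#' Simulate the four cistromes
#'
#' Factor A is treatment-stable. Exactly `round(co_binding_fraction *
#' n_peaks_b)` B peaks are placed inside distinct A peaks (guaranteeing at
#' least 1 bp overlap with exactly one A partner); the remaining peaks of
#' both factors are mutually non-overlapping, so all ground-truth overlap
#' and dynamics counts are exact by construction. The treated B set drops
#' `round(loss_fraction * n_peaks_b)` peaks, scales the intensity of
#' persisting peaks by `treated_intensity_scale` and adds
#' `round(gain_fraction * n_peaks_b)` new low-intensity peaks.
#'
#' @param config a [sim_config()].
#' @param genes gene table from [simulate_genome()] (kept for interface
#'   symmetry; placement does not read it).
#' @return List with `GRanges` peak sets `a_vehicle`, `b_vehicle`,
#'   `a_treated`, `b_treated` and a `truth` list (names of common, lost,
#'   shared and gained B peaks, and the A-B pairing).
#' @export
simulate_cistromes <- function(config, genes = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  n_a <- config$n_peaks_a; n_b <- config$n_peaks_b
  n_common <- round(config$co_binding_fraction * n_b)
  n_gain <- round(config$gain_fraction * n_b)
  draw_w <- function(stream, n) .with_stream(config$seed, stream, {
    pmax(round(stats::rlnorm(n, config$peak_width_log_mean,
                             config$peak_width_log_sd)),
         config$min_peak_width)
  })
  w_a <- draw_w("widths_a", n_a)
  w_b_all <- draw_w("widths_b", n_b + n_gain)
  w_b <- w_b_all[seq_len(n_b)]
  w_gain <- w_b_all[n_b + seq_len(n_gain)]
  draw_i <- function(stream, n, mean, sd) .with_stream(config$seed, stream, {
    pmax(stats::rnorm(n, mean, sd), mean / 20)
  })
  i_a <- draw_i("intensity_a", n_a, config$signal_amplitude_mean,
                config$signal_amplitude_sd)
  i_b <- draw_i("intensity_b", n_b, config$signal_amplitude_mean,
                config$signal_amplitude_sd)
  i_gain <- draw_i("gain_intensity", n_gain,
                   0.3 * config$signal_amplitude_mean,
                   0.3 * config$signal_amplitude_sd)

  a_gr <- .place_peaks(n_a, w_a, config, GenomicRanges::GRanges(),
                       "place_a", config$seed)
  # co-bound B peaks: contained in distinct A partners
  pairing <- .with_stream(config$seed, "pair_common", {
    partner <- sample.int(n_a, n_common)
    offmax <- pmax((w_a[partner] - pmin(w_b[seq_len(n_common)],
                                        w_a[partner])) / 2, 0)
    off <- round(stats::runif(n_common, -offmax, offmax))
    list(partner = partner, off = off)
  })
  b_chrom <- character(n_b); b_start <- numeric(n_b)
  if (n_common > 0) {
    pa <- pairing$partner
    wbc <- pmin(w_b[seq_len(n_common)], w_a[pa])
    w_b[seq_len(n_common)] <- wbc
    ctr_a <- floor((GenomicRanges::start(a_gr)[pa] - 1 +
                    GenomicRanges::end(a_gr)[pa]) / 2)
    ctr_b <- ctr_a + pairing$off
    b_chrom[seq_len(n_common)] <- as.character(GenomicRanges::seqnames(a_gr))[pa]
    b_start[seq_len(n_common)] <- pmax(ctr_b - floor(wbc / 2) + 1, 1)
  }
  n_bu <- n_b - n_common
  if (n_bu > 0) {
    b_common_gr <- if (n_common > 0) {
      GenomicRanges::GRanges(b_chrom[seq_len(n_common)],
                             IRanges::IRanges(b_start[seq_len(n_common)],
                                              width = w_b[seq_len(n_common)]))
    } else GenomicRanges::GRanges()
    bu <- .place_peaks(n_bu, w_b[n_common + seq_len(n_bu)], config,
                       c(a_gr, b_common_gr), "place_b", config$seed)
    b_chrom[n_common + seq_len(n_bu)] <- as.character(GenomicRanges::seqnames(bu))
    b_start[n_common + seq_len(n_bu)] <- GenomicRanges::start(bu)
  }
  b_gr <- GenomicRanges::GRanges(b_chrom, IRanges::IRanges(b_start, width = w_b))

  idw <- function(prefix, n) sprintf("%s_%0*d", prefix,
                                     max(nchar(as.character(max(n, 1))), 1),
                                     seq_len(n))
  a_names <- idw("A", n_a)
  b_names <- idw("B", n_b)
  a_vehicle <- peak_set(as.character(GenomicRanges::seqnames(a_gr)),
                        GenomicRanges::start(a_gr) - 1,
                        GenomicRanges::end(a_gr),
                        name = a_names, score = i_a)
  b_vehicle <- peak_set(as.character(GenomicRanges::seqnames(b_gr)),
                        GenomicRanges::start(b_gr) - 1,
                        GenomicRanges::end(b_gr),
                        name = b_names, score = i_b)
  # treatment dynamics on B
  n_lost <- round(config$loss_fraction * n_b)
  lost_idx <- .with_stream(config$seed, "lose", sample.int(n_b, n_lost))
  shared_idx <- setdiff(seq_len(n_b), lost_idx)
  gained_gr <- .place_peaks(n_gain, w_gain, config, c(a_gr, b_gr),
                            "place_gain", config$seed)
  gain_names <- idw("Bnew", n_gain)
  b_treated <- peak_set(
    c(b_chrom[shared_idx],
      as.character(GenomicRanges::seqnames(gained_gr))),
    c(b_start[shared_idx] - 1, GenomicRanges::start(gained_gr) - 1),
    c(b_start[shared_idx] - 1 + w_b[shared_idx],
      GenomicRanges::end(gained_gr)),
    name = c(b_names[shared_idx], gain_names),
    score = c(i_b[shared_idx] * config$treated_intensity_scale, i_gain)
  )
  a_treated <- a_vehicle
  truth <- list(
    common_b = b_names[seq_len(n_common)],
    pairing = data.frame(b_name = b_names[seq_len(n_common)],
                         a_name = a_names[pairing$partner],
                         stringsAsFactors = FALSE),
    lost_b = b_names[sort(lost_idx)],
    shared_b = b_names[shared_idx],
    gained = gain_names
  )
  list(a_vehicle = a_vehicle, b_vehicle = b_vehicle,
       a_treated = a_treated, b_treated = b_treated, truth = truth)
}

## background + Gaussian bumps track from a peak set; bump SD = width / 4,
## values evaluated at run starts on a `track_resolution` grid and rounded
## to 6 significant digits so text round-trips are exact.
.bumps_track <- function(peaks, config) {
  res <- config$track_resolution
  len <- config$chrom_length
  nbin <- ceiling(len / res)
  cov <- list()
  chroms_p <- as.character(GenomicRanges::seqnames(peaks))
  centers <- floor((GenomicRanges::start(peaks) - 1 +
                    GenomicRanges::end(peaks)) / 2)
  widths <- GenomicRanges::width(peaks)
  amps <- S4Vectors::mcols(peaks)$score
  for (ch in .chrom_names(config)) {
    vec <- rep(config$signal_background, nbin)
    for (i in which(chroms_p == ch)) {
      sdv <- widths[i] / 4
      halfspan <- ceiling(4 * sdv / res)
      cbin <- floor(centers[i] / res)
      i0 <- max(cbin - halfspan, 0); i1 <- min(cbin + halfspan, nbin - 1)
      if (i1 < i0) next
      x <- (i0:i1) * res
      j <- (i0:i1) + 1
      vec[j] <- vec[j] + amps[i] * exp(-(x - centers[i])^2 / (2 * sdv^2))
    }
    vec <- signif(vec, 6)
    lens <- rep(res, nbin)
    lens[nbin] <- len - (nbin - 1) * res
    cov[[ch]] <- S4Vectors::Rle(vec, lens)
  }
  structure(list(cov = cov, resolution = res), class = "SignalTrack")
}

#' Simulate signal tracks
#'
#' One track per mark and condition: `factor_a_*` and `factor_b_*` carry
#' bumps at that factor's peaks, `acetyl_*` (the acetylation-like mark)
#' at the union of both factors' peaks. The value at base x is
#' `background + sum_peaks amplitude * exp(-(x - center)^2 / (2 (width/4)^2))`,
#' evaluated on a `track_resolution` grid.
#'
#' @param peaks list from [simulate_cistromes()].
#' @param config a [sim_config()].
#' @return Named list of six `SignalTrack`s.
#' @export
simulate_tracks <- function(peaks, config) {
  stopifnot(inherits(config, "SimConfig"))
  list(
    factor_a_vehicle = .bumps_track(peaks$a_vehicle, config),
    factor_a_treated = .bumps_track(peaks$a_treated, config),
    factor_b_vehicle = .bumps_track(peaks$b_vehicle, config),
    factor_b_treated = .bumps_track(peaks$b_treated, config),
    acetyl_vehicle = .bumps_track(
      sort_and_validate(c(peaks$a_vehicle, peaks$b_vehicle)), config),
    acetyl_treated = .bumps_track(
      sort_and_validate(c(peaks$a_treated, peaks$b_treated)), config)
  )
}

#' Simulate expression coupled to binding class
#'
#' The planted treatment log2 fold change of a gene is
#' `expr_effect_a * 1[A-bound] - expr_effect_b * 1[B-only]` plus
#' `Normal(0, expr_noise_sd)`; the per-sample matrix adds independent
#' noise of the same SD to each cell. The signature list holds the
#' `signature_size` B-only genes with the largest planted positive B
#' effect (ties broken by gene id).
#'
#' @param genes gene table.
#' @param classes occupancy-class table from [occupancy_classes()]
#'   computed on the synthetic cistromes.
#' @param config a [sim_config()].
#' @return List with `fc` (data.frame `gene_id`, `class`,
#'   `planted_effect`, `log2fc`), `expr_matrix` (genes x samples) and
#'   `signature` (character vector).
#' @export
simulate_expression <- function(genes, classes, config) {
  stopifnot(inherits(config, "SimConfig"))
  stopifnot(identical(genes$gene_id, classes$gene_id))
  cls <- as.character(classes$class)
  planted <- config$expr_effect_a * (cls %in% c("A_only", "common")) -
    config$expr_effect_b * (cls == "B_only")
  n <- nrow(genes)
  fc_noise <- .with_stream(config$seed, "expr_noise",
                           stats::rnorm(n, 0, config$expr_noise_sd))
  log2fc <- planted + fc_noise
  mat_noise <- .with_stream(config$seed, "sample_noise",
                            matrix(stats::rnorm(n * config$n_samples, 0,
                                                config$expr_noise_sd),
                                   nrow = n))
  expr_matrix <- log2fc + mat_noise
  rownames(expr_matrix) <- genes$gene_id
  colnames(expr_matrix) <- sprintf("sample_%d", seq_len(config$n_samples))
  b_only <- genes$gene_id[cls == "B_only"]
  if (config$signature_size > length(b_only))
    stop("signature_size (", config$signature_size,
         ") exceeds the number of B-bound genes (", length(b_only), ")")
  eff <- config$expr_effect_b * rep(1, length(b_only))
  signature <- b_only[order(-eff, b_only)][seq_len(config$signature_size)]
  list(
    fc = data.frame(gene_id = genes$gene_id, class = cls,
                    planted_effect = planted, log2fc = log2fc,
                    stringsAsFactors = FALSE),
    expr_matrix = expr_matrix,
    signature = signature
  )
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genome()], [simulate_cistromes()],
#' [occupancy_classes()] (at `tss_window_kb`), [simulate_expression()]
#' and [simulate_tracks()] under the configured seed.
#'
#' @param config a [sim_config()].
#' @return List with `config`, `genes`, `peaks`, `tracks`, `classes`,
#'   `expression` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genes <- simulate_genome(config)
  peaks <- simulate_cistromes(config, genes)
  classes <- occupancy_classes(genes, peaks$a_vehicle, peaks$b_vehicle,
                               window_kb = config$tss_window_kb)
  expression <- simulate_expression(genes, classes, config)
  tracks <- simulate_tracks(peaks, config)
  list(config = config, genes = genes, peaks = peaks, tracks = tracks,
       classes = classes, expression = expression, truth = peaks$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits BED6 per peak set (score = intensity x 1000, rounded), bedGraph
#' per track, TSV gene/expression tables, the plain-text signature list, a
#' YAML copy of the configuration and a JSON manifest with the seed and
#' per-file MD5 digests.
#'
#' @param dataset list from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  pdir <- file.path(outdir, "peaks"); tdir <- file.path(outdir, "tracks")
  dir.create(pdir, showWarnings = FALSE); dir.create(tdir, showWarnings = FALSE)
  for (nm in c("a_vehicle", "b_vehicle", "a_treated", "b_treated"))
    write_bed(dataset$peaks[[nm]], file.path(pdir, paste0(nm, ".bed")))
  for (nm in names(dataset$tracks))
    write_bedgraph(dataset$tracks[[nm]], file.path(tdir, paste0(nm, ".bedgraph")))
  data.table::fwrite(dataset$genes, file.path(outdir, "genes.tsv"), sep = "\t")
  data.table::fwrite(dataset$expression$fc,
                     file.path(outdir, "expression_fc.tsv"), sep = "\t")
  em <- data.table::data.table(gene_id = rownames(dataset$expression$expr_matrix),
                               dataset$expression$expr_matrix)
  data.table::fwrite(em, file.path(outdir, "expression_matrix.tsv"), sep = "\t")
  writeLines(dataset$expression$signature, file.path(outdir, "signature.txt"))
  cfg <- dataset$config; class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.json"))
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    track_resolution_note = sprintf(
      "bedGraph runs are constant on a %d bp grid", cfg$track_resolution),
    bed_score_scale = 1000,
    files = lapply(stats::setNames(files, sub(paste0("^", outdir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f)))
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a written dataset back into memory
#'
#' Inverse of [write_dataset()]: BED scores are rescaled by the manifest's
#' `bed_score_scale`, so peak intensities round-trip to within the BED
#' score quantum (0.001 by default).
#'
#' @param outdir directory written by [write_dataset()].
#' @return List with `config`, `genes`, `peaks`, `tracks`, `expression`
#'   and `signature`.
#' @export
read_dataset <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(sim_config, manifest$config[names(manifest$config) %in%
                                               names(formals(sim_config))])
  scale <- manifest$bed_score_scale
  peaks <- lapply(stats::setNames(nm = c("a_vehicle", "b_vehicle",
                                         "a_treated", "b_treated")),
                  function(nm) {
    p <- read_bed(file.path(outdir, "peaks", paste0(nm, ".bed")))
    S4Vectors::mcols(p)$score <- S4Vectors::mcols(p)$score / scale
    p
  })
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                          .chrom_names(cfg))
  track_files <- list.files(file.path(outdir, "tracks"),
                            pattern = "\\.bedgraph$")
  tracks <- lapply(stats::setNames(track_files,
                                   sub("\\.bedgraph$", "", track_files)),
                   function(f) read_bedgraph(file.path(outdir, "tracks", f),
                                             chrom_lengths = lens))
  genes <- read_gene_table(file.path(outdir, "genes.tsv"))
  fc <- as.data.frame(data.table::fread(file.path(outdir, "expression_fc.tsv")))
  emdt <- data.table::fread(file.path(outdir, "expression_matrix.tsv"))
  em <- as.matrix(emdt[, -1])
  rownames(em) <- emdt$gene_id
  signature <- readLines(file.path(outdir, "signature.txt"))
  list(config = cfg, genes = genes, peaks = peaks, tracks = tracks,
       expression = list(fc = fc, expr_matrix = em, signature = signature),
       signature = signature)
}
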