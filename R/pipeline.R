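## Configuration-driven orchestration of the full analysis over a dataset
## directory: validation -> overlap partition -> treatment dynamics ->
## occupancy classes -> resampling enrichment -> regulatory-potential
## association -> super-enhancers and fold change -> pileup profiles ->
## signature scores. One TSV per stage plus a JSON summary of headline
## numbers and a JSON manifest; deterministic under a fixed seed.

#' Pipeline configuration
#'
#' @param peaks_a_vehicle,peaks_b_vehicle,peaks_a_treated,peaks_b_treated
#'   BED paths for the two factors in the two conditions.
#' @param track_vehicle,track_treated bedGraph paths for the
#'   acetylation-like signal in the two conditions.
#' @param genes path to the TSV gene table.
#' @param expression_fc path to a TSV with columns `gene_id`, `log2fc`.
#' @param expression_matrix path to a TSV expression matrix
#'   (`gene_id` + one column per sample).
#' @param signature path to a plain-text gene list (one id per line).
#' @param out_dir output directory.
#' @param seed integer seed (mandatory; used by the resampling stage).
#' @param occupancy_window_kb TSS window for occupancy classes (default 10).
#' @param enrichment_window_kb TSS window for resampling enrichment
#'   (default 20).
#' @param rp_half_window regulatory-potential half-window in bases
#'   (default 1e5).
#' @param stitch_distance super-enhancer stitching distance (default 12500).
#' @param n_iter resampling iterations (default 1000).
#' @param flank,bin_width pileup window half-width and bin size in bases
#'   (defaults 2000 and 50).
#' @param fc_up,fc_down,static_band log2 fold-change thresholds defining
#'   up-, down-regulated and static gene classes (defaults 0.5, -0.5, 0.1).
#' @param pseudocount pseudocount for super-enhancer fold changes
#'   (default 1).
#' @return List of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(peaks_a_vehicle, peaks_b_vehicle,
                            peaks_a_treated, peaks_b_treated,
                            track_vehicle, track_treated,
                            genes, expression_fc, expression_matrix,
                            signature, out_dir, seed,
                            occupancy_window_kb = 10,
                            enrichment_window_kb = 20,
                            rp_half_window = 1e5,
                            stitch_distance = 12500,
                            n_iter = 1000,
                            flank = 2000, bin_width = 50,
                            fc_up = 0.5, fc_down = -0.5, static_band = 0.1,
                            pseudocount = 1) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for the resampling stage")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("PipelineConfig", "list"))
}

## one pipeline_config pointing at the files written by write_dataset()
#' Pipeline configuration for a written synthetic dataset
#'
#' @param dataset_dir directory written by [write_dataset()].
#' @param out_dir pipeline output directory.
#' @param seed integer seed.
#' @param ... further arguments passed to [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
dataset_pipeline_config <- function(dataset_dir, out_dir, seed, ...) {
  p <- function(...) file.path(dataset_dir, ...)
  pipeline_config(
    peaks_a_vehicle = p("peaks", "a_vehicle.bed"),
    peaks_b_vehicle = p("peaks", "b_vehicle.bed"),
    peaks_a_treated = p("peaks", "a_treated.bed"),
    peaks_b_treated = p("peaks", "b_treated.bed"),
    track_vehicle = p("tracks", "acetyl_vehicle.bedgraph"),
    track_treated = p("tracks", "acetyl_treated.bedgraph"),
    genes = p("genes.tsv"),
    expression_fc = p("expression_fc.tsv"),
    expression_matrix = p("expression_matrix.tsv"),
    signature = p("signature.txt"),
    out_dir = out_dir, seed = seed, ...
  )
}

.stage_tsv <- function(df, path, stage, params) {
  hdr <- c(sprintf("# stage: %s", stage),
           sprintf("# %s", paste(names(params), unlist(params),
                                 sep = "=", collapse = "; ")))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  data.table::fwrite(df, tmp, sep = "\t", col.names = TRUE)
  writeLines(hdr, path)
  file.append(path, tmp)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input validation, peak-set overlap partition,
#' treatment dynamics, gene occupancy classes with class-wise expression
#' comparison, resampling enrichment of the up- and down-regulated gene
#' sets against both cistromes, regulatory-potential association,
#' super-enhancer calling with per-region fold change, pileup profiles at
#' the partitioned peak classes, and per-sample signature scores. Each
#' stage writes a self-describing TSV under `out_dir`; headline numbers go
#' to `summary.json` and run metadata to `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  infiles <- c("peaks_a_vehicle", "peaks_b_vehicle", "peaks_a_treated",
               "peaks_b_treated", "track_vehicle", "track_treated",
               "genes", "expression_fc", "expression_matrix", "signature")
  for (f in infiles)
    if (!file.exists(config[[f]]))
      stop("pipeline input missing: ", f, " (", config[[f]], ")")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- "validation"
  summary <- list(seed = config$seed)
  tryCatch({
    a_veh <- read_bed(config$peaks_a_vehicle)
    b_veh <- read_bed(config$peaks_b_vehicle)
    a_trt <- read_bed(config$peaks_a_treated)
    b_trt <- read_bed(config$peaks_b_treated)
    genes <- read_gene_table(config$genes)
    fc <- as.data.frame(data.table::fread(config$expression_fc))
    if (!all(c("gene_id", "log2fc") %in% names(fc)))
      stop("expression_fc must have columns gene_id, log2fc")
    emdt <- data.table::fread(config$expression_matrix)
    expr <- as.matrix(emdt[, -1]); rownames(expr) <- emdt[[1]]
    signature <- readLines(config$signature)
    trk_veh <- read_bedgraph(config$track_vehicle)
    trk_trt <- read_bedgraph(config$track_treated)

    stage <- "overlap_partition"
    part <- intersect_partition(a_veh, b_veh)
    counts <- vapply(part[c("a_unique", "a_common", "b_unique", "b_common")],
                     length, 0L)
    .stage_tsv(data.frame(set = names(counts), n_peaks = unname(counts)),
               out("overlap_partition.tsv"), stage,
               list(a = config$peaks_a_vehicle, b = config$peaks_b_vehicle))
    summary$overlap <- as.list(counts)
    summary$overlap$common_b_fraction <- counts[["b_common"]] / length(b_veh)

    stage <- "dynamics"
    dyn <- classify_dynamics(b_veh, b_trt)
    dcounts <- vapply(dyn[c("lost", "shared", "gained")], length, 0L)
    .stage_tsv(data.frame(set = names(dcounts), n_peaks = unname(dcounts)),
               out("dynamics.tsv"), stage,
               list(vehicle = config$peaks_b_vehicle,
                    treated = config$peaks_b_treated))
    summary$dynamics <- as.list(dcounts)

    stage <- "occupancy_classes"
    classes <- occupancy_classes(genes, a_veh, b_veh,
                                 window_kb = config$occupancy_window_kb)
    .stage_tsv(classes, out("occupancy_classes.tsv"), stage,
               list(window_kb = config$occupancy_window_kb))
    summary$occupancy <- as.list(table(classes$class))
    fcm <- fc[match(classes$gene_id, fc$gene_id), ]
    byclass <- split(fcm$log2fc, classes$class)
    byclass <- byclass[vapply(byclass, length, 0L) >= 3]
    if (length(byclass) >= 2) {
      cmp <- compare_groups(byclass)
      .stage_tsv(cmp, out("class_fc_comparison.tsv"), stage,
                 list(test = "two-sided Wilcoxon rank-sum, BH-adjusted"))
    }

    stage <- "resampling_enrichment"
    up <- fc$gene_id[fc$log2fc >= config$fc_up]
    down <- fc$gene_id[fc$log2fc <= config$fc_down]
    enr <- list()
    combos <- list(
      up_vs_a = list(q = up, p = a_veh, s = 1L),
      down_vs_a = list(q = down, p = a_veh, s = 2L),
      up_vs_b = list(q = up, p = b_veh, s = 3L),
      down_vs_b = list(q = down, p = b_veh, s = 4L)
    )
    for (nm in names(combos)) {
      co <- combos[[nm]]
      if (length(co$q) == 0) next
      e <- resample_enrichment(co$q, co$p, genes,
                               window_kb = config$enrichment_window_kb,
                               n_iter = config$n_iter,
                               seed = config$seed + co$s)
      enr[[nm]] <- data.frame(
        comparison = nm, n_query = e$n_query,
        observed_pct = e$observed_pct, null_mean_pct = mean(e$null_pcts),
        odds_ratio = e$odds_ratio, p_empirical = e$p_empirical,
        p_t = e$p_t, seed = e$seed)
    }
    enr_df <- do.call(rbind, enr)
    .stage_tsv(enr_df, out("enrichment.tsv"), stage,
               list(window_kb = config$enrichment_window_kb,
                    n_iter = config$n_iter, seed = config$seed))
    summary$enrichment <- lapply(enr, function(d)
      list(odds_ratio = d$odds_ratio, p_empirical = d$p_empirical))

    stage <- "regulatory_potential"
    static <- setdiff(fc$gene_id[abs(fc$log2fc) <= config$static_band],
                      c(up, down))
    rp <- regulatory_potential(genes, a_veh,
                               half_window = config$rp_half_window)
    .stage_tsv(rp, out("regulatory_potential.tsv"), stage,
               list(peaks = config$peaks_a_vehicle,
                    half_window = config$rp_half_window))
    assoc <- beta_association(rp, up, down, static)
    .stage_tsv(assoc$tests, out("rp_association.tsv"), stage,
               list(n_up = length(up), n_down = length(down),
                    n_static = length(static)))
    summary$rp_association <- stats::setNames(
      as.list(assoc$tests$p_value), assoc$tests$class)

    stage <- "superenhancer"
    enh <- sort_and_validate(c(a_veh, b_veh))
    stitched <- stitch_peaks(enh, stitch_distance = config$stitch_distance)
    ranking <- rank_enhancers(stitched, track = trk_veh)
    fc_se <- se_fold_change(ranking, trk_veh, trk_trt,
                            pseudocount = config$pseudocount)
    # regions whose constituents are all persisting (shared) B peaks
    shared_names <- S4Vectors::mcols(dyn$shared)$name
    const_names <- lapply(S4Vectors::mcols(ranking$regions)$revmap,
                          function(i) S4Vectors::mcols(enh)$name[i])
    b_dom <- vapply(const_names, function(nm) all(nm %in% shared_names),
                    TRUE)
    ord <- match(S4Vectors::mcols(ranking$regions)$name, fc_se$name)
    se_tab <- data.frame(
      name = S4Vectors::mcols(ranking$regions)$name,
      chrom = as.character(GenomicRanges::seqnames(ranking$regions)),
      start = GenomicRanges::start(ranking$regions) - 1L,
      end = GenomicRanges::end(ranking$regions),
      n_constituents = S4Vectors::mcols(ranking$regions)$n_constituents,
      total_signal = S4Vectors::mcols(ranking$regions)$total_signal,
      rank = S4Vectors::mcols(ranking$regions)$rank,
      is_super = S4Vectors::mcols(ranking$regions)$is_super,
      log2fc = fc_se$log2fc[ord],
      b_dominated = b_dom)
    .stage_tsv(se_tab, out("superenhancers.tsv"), stage,
               list(stitch_distance = config$stitch_distance,
                    pseudocount = config$pseudocount))
    summary$superenhancer <- list(
      n_regions = length(ranking$regions),
      n_super = ranking$n_super,
      cutoff_signal = ranking$cutoff_signal,
      median_log2fc = stats::median(se_tab$log2fc),
      median_log2fc_b_dominated =
        if (any(b_dom)) stats::median(se_tab$log2fc[b_dom]) else NA_real_,
      n_b_dominated = sum(b_dom))

    stage <- "profiles"
    prof_sets <- list(common = part$b_common, a_unique = part$a_unique,
                      b_unique = part$b_unique)
    prof_rows <- list()
    for (nm in names(prof_sets)) {
      if (length(prof_sets[[nm]]) == 0) next
      pm <- profile_matrix(prof_sets[[nm]], trk_veh,
                           flank = config$flank,
                           bin_width = config$bin_width)
      prof_rows[[nm]] <- c(set = nm, as.list(mean_profile(pm)))
    }
    prof_df <- data.table::rbindlist(prof_rows)
    data.table::setnames(prof_df, c("set", sprintf("bin_%d",
                                                   seq_len(ncol(prof_df) - 1))))
    .stage_tsv(prof_df, out("profiles.tsv"), stage,
               list(flank = config$flank, bin_width = config$bin_width,
                    track = config$track_vehicle))
    summary$profiles <- list(n_bins = ncol(prof_df) - 1L)

    stage <- "signature"
    scores <- signature_zscore(expr, signature)
    .stage_tsv(scores, out("signature_scores.tsv"), stage,
               list(n_signature = length(signature)))
    summary$signature <- list(n_genes_used = scores$n_genes_used[1],
                              score_sum = sum(scores$score))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    config = unclass(config),
    input_md5 = lapply(stats::setNames(nm = infiles),
                       function(f) unname(tools::md5sum(config[[f]]))),
    stage_order = c("overlap_partition", "dynamics", "occupancy_classes",
                    "resampling_enrichment", "regulatory_potential",
                    "superenhancer", "profiles", "signature")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
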