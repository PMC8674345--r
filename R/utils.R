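## Internal helpers: RNG discipline.
##
## Seeded operations restore the caller's RNG state on exit, and the
## synthetic-data generator derives one named substream per stochastic
## stage from the master seed so adding a stage never perturbs the draws
## of earlier stages.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## fixed registry of substream offsets; order is append-only
.stream_offsets <- c(
  genome = 1L, widths_a = 2L, widths_b = 3L, intensity_a = 4L,
  intensity_b = 5L, place_a = 6L, place_b = 7L, pair_common = 8L,
  place_gain = 9L, lose = 10L, gain_intensity = 11L,
  expr_noise = 12L, sample_noise = 13L, strands = 14L
)

## derive a deterministic 31-bit substream seed
.stream_seed <- function(seed, stream) {
  off <- .stream_offsets[[stream]]
  if (is.null(off)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

## evaluate expr under a named substream, restoring RNG state afterwards
.with_stream <- function(seed, stream, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.stream_seed(seed, stream))
  expr
}
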