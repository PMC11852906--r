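# Internal helpers: reproducible seed substreams and interval conversion.

#' Derive a deterministic child seed from a base seed and a key
#'
#' A small multiplicative string hash modulo 2^31 - 1. Used to give every
#' simulated chromosome, patient and resampling round its own RNG substream
#' so that, e.g., adding validation samples never perturbs discovery samples.
#'
#' @param seed base integer seed
#' @param ... key components (coerced to character)
#' @return an integer seed in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# data.frame(chrom, start, end) [1-based inclusive] -> GRanges
regions_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

# Positions -> width-1 GRanges
positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}

# Sort order by chromosome name then position (chromosome names compared
# as plain strings; synthetic and UCSC-style names both sort stably).
order_sites <- function(chrom, pos) order(chrom, pos)
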