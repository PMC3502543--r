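# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All user-facing stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage child seeds derived from one run seed, kept within
# 32-bit integer range so set.seed() accepts them on any platform.
stage_seed <- function(seed, stage) {
  stages <- c(
    "peaks" = 11L, "counts" = 23L, "annotations" = 37L, "alignments" = 53L,
    "calls" = 67L, "clustering" = 83L, "overlap" = 97L, "footprint" = 113L
  )
  off <- stages[[stage]]
  as.integer((as.double(seed) * 131L + off) %% 2147483587)
}

# Wide matrix tibble (first column peak_id, one column per sample) -> base
# numeric matrix with peak ids as rownames.
matrix_from_tbl <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "peak_id")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$peak_id
  m
}

tbl_from_matrix <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(peak_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Column-subset helper: sample ids for a metadata predicate, restricted to
# those actually present in the matrix tibble.
samples_in <- function(tbl, sample_ids) {
  intersect(names(tbl)[-1], sample_ids)
}

`%||%` <- rlang::`%||%`
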