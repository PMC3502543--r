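# Small in-code fixtures shared across test files.

toy_layout <- function(n_chrom = 2, len = 5e6) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom), "synth1")
}

make_peaks <- function(starts, lengths = 1000, chrom = "chr1",
                       layout = toy_layout()) {
  n <- length(starts)
  validate_peaks(tibble::tibble(
    peak_id = paste0("pk", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = starts,
    end = starts + rep_len(lengths, n)
  ), layout)
}

# density tibble from a named list of per-sample value vectors
make_density <- function(values, peak_ids = NULL) {
  n <- length(values[[1]])
  peak_ids <- peak_ids %||% paste0("pk", seq_len(n))
  tibble::as_tibble(c(list(peak_id = peak_ids), values))
}

# metadata for an arbitrary set of sample columns
make_samples <- function(ids, species, cell_type = "NeuN+",
                         library_size = 1e7) {
  chromdiver::validate_samples(tibble::tibble(
    sample_id = ids, species = species,
    cell_type = rep_len(cell_type, length(ids)),
    library_size = rep_len(library_size, length(ids)),
    age_group = "unknown"
  ))
}

# five-taxon alignment block from per-taxon strings
make_block <- function(human, comparison, peak_id = "pk1",
                       comparison_taxa = c("chimpanzee", "gorilla",
                                           "orangutan", "macaque"),
                       extra = NULL) {
  if (length(comparison) == 1) {
    comparison <- rep(comparison, length(comparison_taxa))
  }
  tb <- tibble::tibble(
    peak_id = peak_id,
    taxon = c("human", comparison_taxa, names(extra)),
    seq = c(human, comparison, unlist(extra, use.names = FALSE))
  )
  validate_alignment_blocks(tb)
}

random_peaks <- function(n, layout = toy_layout(3), min_len = 200,
                         max_len = 2000) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, min(layout$length) - max_len))
  validate_peaks(tibble::tibble(
    peak_id = paste0("rp", seq_len(n)), chrom = chrom,
    start = start, end = start + len), layout)
}

random_annot <- function(n, layout = toy_layout(3), max_len = 3000) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- sample(50:max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, min(layout$length) - max_len))
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
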