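# Readers/writers for the plain-text formats the pipeline touches (BED,
# TSV tables, aligned multi-FASTA) plus the validators that turn them into
# the package's tabular domain types. Coordinates are 0-based half-open
# (BED convention) everywhere internally.

.species_vocab <- c("human", "chimpanzee", "macaque")
.cell_type_vocab <- c("NeuN+", "NeuN-", "blood", "input")
.age_vocab <- c("child", "adult", "unknown")
.aln_alphabet <- c("A", "C", "G", "T", "N", "-")

#' Define a genome layout
#'
#' A layout names the chromosomes of an assembly and their lengths; every
#' interval the pipeline handles is validated against it.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer vector of chromosome lengths (bp).
#' @param assembly Free-text assembly label (e.g. `"HG19"`, `"synth1"`).
#' @return A tibble with columns `chrom`, `length` and attribute `assembly`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6), "synth1")
#' @export
genome_layout <- function(chrom, length, assembly = "custom") {
  chrom <- as.character(chrom)
  length <- as.double(length)
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(!is.finite(length) | length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  out <- tibble(chrom = chrom, length = length)
  attr(out, "assembly") <- as.character(assembly)[1]
  class(out) <- c("genome_layout", class(out))
  out
}

#' Validate a peak table against a layout
#'
#' @param peaks Tibble with columns `peak_id`, `chrom`, `start`, `end`.
#' @param layout A [genome_layout()].
#' @return The validated tibble with a `length` column added.
#' @export
validate_peaks <- function(peaks, layout) {
  peaks <- as_tibble(peaks)
  need <- c("peak_id", "chrom", "start", "end")
  if (!all(need %in% names(peaks))) {
    abort(paste("peak table must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(peaks$peak_id)) abort("peak ids must be unique")
  bad <- which(!(peaks$chrom %in% layout$chrom))
  if (length(bad)) {
    abort(sprintf("unknown chromosome '%s' (record %d)",
                  peaks$chrom[bad[1]], bad[1]))
  }
  clen <- setNames(layout$length, layout$chrom)[peaks$chrom]
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end & peaks$end <= clen))
  if (length(bad)) {
    abort(sprintf(
      "malformed interval at record %d: %s:%s-%s (chromosome length %s)",
      bad[1], peaks$chrom[bad[1]], format(peaks$start[bad[1]], scientific = FALSE),
      format(peaks$end[bad[1]], scientific = FALSE),
      format(clen[bad[1]], scientific = FALSE)
    ))
  }
  mutate(peaks, length = .data$end - .data$start)
}

#' Read peaks from a BED3/BED4 file
#'
#' The optional fourth column is used as the peak id; otherwise ids
#' `peak_1 .. peak_n` are assigned in file order.
#'
#' @param path BED file (tab-separated, no header).
#' @param layout A [genome_layout()] the records must fall within.
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `length`, in file order.
#' @export
read_peaks <- function(path, layout) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  peaks <- tibble(
    peak_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      paste0("peak_", seq_len(nrow(raw))),
    chrom = as.character(raw[[1]]),
    start = as.double(raw[[2]]),
    end = as.double(raw[[3]])
  )
  validate_peaks(peaks, layout)
}

#' Write peaks as BED4
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(
    tibble(peaks$chrom,
           format(peaks$start, scientific = FALSE, trim = TRUE),
           format(peaks$end, scientific = FALSE, trim = TRUE),
           peaks$peak_id),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read an annotation interval set from BED
#'
#' @inheritParams read_peaks
#' @param name Name for the annotation track.
#' @return Tibble `chrom`, `start`, `end` with attribute `name`. Intervals
#'   may overlap each other.
#' @export
read_annotations <- function(path, layout, name = basename(path)) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.double(raw[[2]]), end = as.double(raw[[3]]))
  clen <- setNames(layout$length, layout$chrom)
  if (any(!(out$chrom %in% layout$chrom))) abort("annotation on unknown chromosome")
  if (any(out$start < 0 | out$start >= out$end | out$end > clen[out$chrom])) {
    abort("annotation interval outside layout")
  }
  attr(out, "name") <- name
  out
}

#' Read the sample metadata table
#'
#' Expects a TSV with header columns `sample_id`, `species`, `cell_type`,
#' `library_size` and optionally `age_group`. Species must be one of
#' human/chimpanzee/macaque; cell types one of NeuN+/NeuN-/blood/input
#' (mononucleosomal input libraries ride the same metadata path).
#'
#' @param path TSV file with header.
#' @return Tibble of sample metadata; `age_group` defaults to `"unknown"`.
#' @export
read_sample_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "species", "cell_type", "library_size")
  if (!all(need %in% names(raw))) {
    abort(paste("sample table must have columns:", paste(need, collapse = ", ")))
  }
  if (!"age_group" %in% names(raw)) raw$age_group <- "unknown"
  raw$age_group[is.na(raw$age_group)] <- "unknown"
  validate_samples(as_tibble(raw[, c(need, "age_group")]))
}

#' Validate a sample metadata tibble
#'
#' @param samples Tibble with the sample-table columns.
#' @return The validated tibble.
#' @export
validate_samples <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf("duplicate sample_id '%s'",
                  samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  bad <- setdiff(samples$species, .species_vocab)
  if (length(bad)) abort(sprintf("unknown species '%s'", bad[1]))
  bad <- setdiff(samples$cell_type, .cell_type_vocab)
  if (length(bad)) abort(sprintf("unknown cell_type '%s'", bad[1]))
  bad <- setdiff(samples$age_group, .age_vocab)
  if (length(bad)) abort(sprintf("unknown age_group '%s'", bad[1]))
  if (any(!is.finite(samples$library_size) | samples$library_size <= 0)) {
    abort("library_size must be positive")
  }
  samples
}

#' Read a peak-by-sample count matrix
#'
#' TSV with header; first column `peak_id`, remaining columns one per
#' sample, entries raw tag counts.
#'
#' @param path TSV file.
#' @param peaks Optional peak tibble: ids must match exactly (order too).
#' @param samples Optional sample tibble: every matrix column needs metadata.
#' @return Wide tibble (`peak_id` + one numeric column per sample).
#' @export
read_count_matrix <- function(path, peaks = NULL, samples = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "peak_id"
  raw$peak_id <- as.character(raw$peak_id)
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) abort("counts must be non-negative and complete")
  if (!is.null(peaks) && !identical(raw$peak_id, peaks$peak_id)) {
    abort("count matrix peak ids do not match the peak set")
  }
  if (!is.null(samples)) {
    missing <- setdiff(names(raw)[-1], samples$sample_id)
    if (length(missing)) {
      abort(sprintf("matrix sample '%s' missing from metadata", missing[1]))
    }
  }
  as_tibble(raw)
}

#' Write a wide matrix tibble as TSV
#'
#' @param tbl Wide matrix tibble (counts or densities).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read per-peak alignment blocks from aligned multi-FASTA
#'
#' Headers are `>taxon|peak_id`. Each block (all records sharing a peak id)
#' must contain a `human` row, use only `A,C,G,T,N,-`, and have equal
#' sequence lengths (alignment columns). Sequences are upper-cased.
#'
#' @param path Aligned multi-FASTA file.
#' @return Long tibble `peak_id`, `taxon`, `seq` (one row per taxon per block).
#' @export
read_alignment_blocks <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(set), "|", fixed = TRUE)
  if (any(lengths(hdr) != 2)) abort("FASTA headers must be 'taxon|peak_id'")
  blocks <- tibble(
    peak_id = vapply(hdr, `[`, "", 2),
    taxon = vapply(hdr, `[`, "", 1),
    seq = unname(toupper(as.character(set)))
  )
  validate_alignment_blocks(blocks)
}

#' Validate alignment blocks
#'
#' @param blocks Long tibble `peak_id`, `taxon`, `seq`.
#' @return The validated tibble.
#' @export
validate_alignment_blocks <- function(blocks) {
  blocks <- as_tibble(blocks)
  bad <- grepl(sprintf("[^%s]", paste(.aln_alphabet, collapse = "")), blocks$seq)
  if (any(bad)) {
    abort(sprintf("illegal character in sequence for peak '%s' taxon '%s'",
                  blocks$peak_id[bad][1], blocks$taxon[bad][1]))
  }
  chk <- blocks |>
    group_by(.data$peak_id) |>
    summarise(n_len = dplyr::n_distinct(nchar(.data$seq)),
              has_human = any(.data$taxon == "human"),
              dup = anyDuplicated(.data$taxon) > 0, .groups = "drop")
  if (any(chk$n_len > 1)) {
    abort(sprintf("unequal sequence lengths within block '%s'",
                  chk$peak_id[chk$n_len > 1][1]))
  }
  if (any(!chk$has_human)) {
    abort(sprintf("block '%s' lacks a human record",
                  chk$peak_id[!chk$has_human][1]))
  }
  if (any(chk$dup)) {
    abort(sprintf("duplicate taxon within block '%s'", chk$peak_id[chk$dup][1]))
  }
  blocks
}

#' Write alignment blocks as aligned multi-FASTA
#'
#' @param blocks Long tibble `peak_id`, `taxon`, `seq`.
#' @param path Output path.
#' @export
write_alignment_blocks <- function(blocks, path) {
  set <- Biostrings::BStringSet(setNames(blocks$seq,
                                         paste(blocks$taxon, blocks$peak_id, sep = "|")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
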