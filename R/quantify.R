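# Tag-count normalization and sample-to-sample correlation structure.
#
# Densities are expressed in ppm per kb: tags per million mapped tags in the
# sample, further divided by peak length in kb so peaks of different lengths
# are comparable. Raw ppm (no length term) is available for display.

#' Normalize raw tag counts to densities
#'
#' `density(p, s) = count(p, s) / (library_size(s) / 1e6) / (length(p) / 1e3)`
#' for unit `"ppm_per_kb"`; the length term is dropped for `"ppm"`.
#'
#' @param counts Wide count tibble (`peak_id` + one column per sample).
#' @param samples Sample metadata tibble with `library_size`.
#' @param peaks Peak tibble supplying peak lengths.
#' @param unit `"ppm_per_kb"` (default, used for classification) or `"ppm"`.
#' @return Wide density tibble of the same shape, attribute `unit` set.
#' @examples
#' layout <- genome_layout("chr1", 1e6)
#' peaks <- validate_peaks(
#'   tibble::tibble(peak_id = "pk1", chrom = "chr1", start = 0, end = 1500),
#'   layout)
#' samples <- tibble::tibble(sample_id = "H1", species = "human",
#'   cell_type = "NeuN+", library_size = 1e7, age_group = "unknown")
#' counts <- tibble::tibble(peak_id = "pk1", H1 = 30)
#' normalize_density(counts, samples, peaks)  # 30/10/1.5 = 2 ppm/kb
#' @export
normalize_density <- function(counts, samples, peaks,
                              unit = c("ppm_per_kb", "ppm")) {
  unit <- match.arg(unit)
  sample_ids <- names(counts)[-1]
  missing <- setdiff(sample_ids, samples$sample_id)
  if (length(missing)) {
    abort(sprintf("sample '%s' missing from metadata", missing[1]))
  }
  if (!all(counts$peak_id %in% peaks$peak_id)) {
    abort("count matrix contains peaks absent from the peak set")
  }
  m <- matrix_from_tbl(counts)
  lib <- setNames(samples$library_size, samples$sample_id)[sample_ids]
  len <- setNames(peaks$length, peaks$peak_id)[counts$peak_id]
  m <- sweep(m, 2, lib / 1e6, "/")
  if (unit == "ppm_per_kb") m <- sweep(m, 1, len / 1e3, "/")
  out <- tbl_from_matrix(m)
  attr(out, "unit") <- unit
  out
}

#' Correct densities for input (mononucleosomal background) signal
#'
#' Rescales each peak's densities by the ratio of the mean input density to
#' that peak's input density: `corrected(p, s) = density(p, s) *
#' mean(input) / (input(p) + pseudo)`. Off by default in the pipeline
#' (pass-through); enable it when an input library is available.
#'
#' @param density Wide density tibble.
#' @param input_density Tibble `peak_id`, `density` (per-peak input density)
#'   covering every peak, or a named numeric vector.
#' @param pseudo Small positive stabilizer added to the denominator.
#' @return Corrected wide density tibble.
#' @export
input_correct <- function(density, input_density, pseudo = 0.1) {
  if (pseudo < 0) abort("pseudo must be non-negative")
  if (is.data.frame(input_density)) {
    input_density <- setNames(input_density$density, input_density$peak_id)
  }
  if (!all(density$peak_id %in% names(input_density))) {
    abort("input densities must cover all peaks")
  }
  inp <- input_density[density$peak_id]
  m <- matrix_from_tbl(density)
  m <- sweep(m, 1, mean(inp) / (inp + pseudo), "*")
  out <- tbl_from_matrix(m)
  attr(out, "unit") <- attr(density, "unit")
  out
}

#' Pairwise sample correlations over peak densities
#'
#' Pearson correlation of every sample pair over the chosen peak rows
#' (optionally a subset, e.g. conserved promoter peaks). Samples with zero
#' variance over the subset yield `NA` correlations and are flagged with a
#' warning rather than silently coerced.
#'
#' @param density Wide density (or count) tibble.
#' @param subset Optional character vector of peak ids to restrict to.
#' @param method Correlation method, default `"pearson"`.
#' @return A symmetric correlation matrix (class `cor_matrix`) with unit
#'   diagonal.
#' @export
sample_correlations <- function(density, subset = NULL, method = "pearson") {
  m <- matrix_from_tbl(density)
  if (!is.null(subset)) {
    missing <- setdiff(subset, rownames(m))
    if (length(missing)) abort(sprintf("subset peak '%s' not in matrix", missing[1]))
    m <- m[subset, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 peaks to correlate samples")
  v <- apply(m, 2, sd)
  if (any(v == 0)) {
    warn(sprintf("zero-variance sample(s): %s; their correlations are NA",
                 paste(colnames(m)[v == 0], collapse = ", ")))
  }
  r <- suppressWarnings(cor(m, method = method))
  diag(r) <- 1
  class(r) <- c("cor_matrix", class(r))
  r
}

#' Summarise correlations within and between sample groups
#'
#' Mean and SD of the pairwise correlation coefficient for every pair of
#' sample groups (species x cell type by default), the usual companion to a
#' sample-to-sample correlation heatmap.
#'
#' @param cors A `cor_matrix` from [sample_correlations()].
#' @param samples Sample metadata tibble.
#' @param grouping Metadata columns defining the groups.
#' @return Tibble `group_a`, `group_b`, `n_pairs`, `mean_r`, `sd_r`.
#' @export
summarize_correlations <- function(cors, samples,
                                   grouping = c("species", "cell_type")) {
  ids <- colnames(cors)
  meta <- samples[match(ids, samples$sample_id), , drop = FALSE]
  grp <- do.call(paste, c(meta[grouping], sep = "/"))
  pairs <- which(upper.tri(cors), arr.ind = TRUE)
  tibble(
    group_a = pmin(grp[pairs[, 1]], grp[pairs[, 2]]),
    group_b = pmax(grp[pairs[, 1]], grp[pairs[, 2]]),
    r = cors[pairs]
  ) |>
    group_by(.data$group_a, .data$group_b) |>
    summarise(n_pairs = n(), mean_r = mean(.data$r), sd_r = sd(.data$r),
              .groups = "drop")
}

#' @export
tidy.cor_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = colnames(x)[pairs[, 1]],
         sample_b = colnames(x)[pairs[, 2]],
         r = x[pairs])
}

#' Correlation heatmap
#'
#' @param object A `cor_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cor_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("sample_a", "sample_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
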