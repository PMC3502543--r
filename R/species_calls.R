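# Species-specific gain/loss classification of peaks from normalized
# densities: fold + length filters combined with a per-peak rank-sum test
# and Benjamini-Hochberg FDR control, the reciprocal depletion procedure,
# the neuronal (cell-type) restriction, call-set intersection, and
# selection of least-divergent control peaks.

#' Analysis configuration
#'
#' Thresholds for the classification and permutation stages. All of them
#' live here; no stage carries hidden constants.
#'
#' @param fold_threshold Minimum fold change `F` (must exceed 1). 2.0 for
#'   the primary screen; 1.5 for the secondary (adult-cohort) screen.
#' @param min_length Minimum peak length `L` in bp (default 500).
#' @param fdr_alpha Benjamini-Hochberg FDR level (default 0.05).
#' @param pseudo_density Pseudo-density `epsilon` in ppm/kb added to group
#'   means before folds, preventing infinite folds on zero-background peaks.
#' @param fold_mode `"each_species"`: the fold filter must pass against each
#'   comparison species' mean (stricter conjunction); `"pooled_average"`:
#'   against the mean over all pooled comparison samples.
#' @param presence_floor Depletion candidate universe: minimum pooled
#'   comparison-species mean density (ppm/kb) for a peak to count as
#'   "detected" in the comparison species.
#' @param distance_thresholds Pairing distances d in bp for the
#'   co-localization statistic.
#' @param n_sims Number of resampling draws for permutation tests.
#' @param rng_seed Seed recorded with every run.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fold_threshold = 2.0,
                            min_length = 500,
                            fdr_alpha = 0.05,
                            pseudo_density = 0.1,
                            fold_mode = c("each_species", "pooled_average"),
                            presence_floor = 1.0,
                            distance_thresholds = c(1e6, 5e5),
                            n_sims = 10000,
                            rng_seed = 1L) {
  fold_mode <- match.arg(fold_mode)
  stopifnot(fold_threshold > 1, min_length >= 1,
            fdr_alpha > 0, fdr_alpha < 1, pseudo_density > 0, n_sims >= 1)
  structure(list(
    fold_threshold = fold_threshold, min_length = min_length,
    fdr_alpha = fdr_alpha, pseudo_density = pseudo_density,
    fold_mode = fold_mode, presence_floor = presence_floor,
    distance_thresholds = distance_thresholds, n_sims = n_sims,
    rng_seed = rng_seed
  ), class = "analysis_config")
}

# Row means of the density matrix over one sample group; NULL if no samples.
group_means <- function(m, ids) {
  if (!length(ids)) return(NULL)
  rowMeans(m[, ids, drop = FALSE])
}

# Two-sided rank-sum p-values, one peak (row) at a time. Exact when the
# smaller group has <= 12 samples and there are no ties, else the normal
# approximation with continuity correction (wilcox.test's behavior).
ranksum_rows <- function(m, ids_a, ids_b) {
  exact <- min(length(ids_a), length(ids_b)) <= 12
  a <- m[, ids_a, drop = FALSE]
  b <- m[, ids_b, drop = FALSE]
  vapply(seq_len(nrow(m)), function(i) {
    suppressWarnings(
      wilcox.test(a[i, ], b[i, ], exact = exact, correct = TRUE)$p.value
    )
  }, numeric(1))
}

call_engine <- function(density, samples, peaks, target_species,
                        comparison_species, cfg, direction,
                        cell_type = "NeuN+", universe = NULL) {
  samples <- validate_samples(samples)
  m <- matrix_from_tbl(density)
  use <- samples[samples$cell_type == cell_type &
                   samples$species %in% c(target_species, comparison_species), ]
  ids_by_species <- split(use$sample_id, use$species)
  ids_by_species <- lapply(ids_by_species, intersect, x = colnames(m))
  tgt_ids <- ids_by_species[[target_species]] %||% character()
  comp_ids_list <- ids_by_species[comparison_species]
  if (length(tgt_ids) < 2 || any(lengths(comp_ids_list) < 2)) {
    abort("each species group needs at least 2 samples in the matrix")
  }
  if (!all(rownames(m) %in% peaks$peak_id)) {
    abort("density matrix contains peaks absent from the peak set")
  }
  len <- setNames(peaks$length, peaks$peak_id)[rownames(m)]
  eps <- cfg$pseudo_density

  tgt_mean <- group_means(m, tgt_ids)
  comp_means <- lapply(comp_ids_list, group_means, m = m)
  pooled_ids <- unlist(comp_ids_list, use.names = FALSE)
  pooled_mean <- group_means(m, pooled_ids)

  # fold in the called direction: gain puts the target on top
  fold_of <- function(num, den) (num + eps) / (den + eps)
  if (direction == "gain") {
    folds <- lapply(comp_means, function(cm) fold_of(tgt_mean, cm))
    fold_pooled <- fold_of(tgt_mean, pooled_mean)
  } else {
    folds <- lapply(comp_means, function(cm) fold_of(cm, tgt_mean))
    fold_pooled <- fold_of(pooled_mean, tgt_mean)
  }
  fold_eff <- if (cfg$fold_mode == "each_species") {
    do.call(pmin, folds)
  } else {
    fold_pooled
  }

  if (is.null(universe)) {
    universe <- if (direction == "gain") rownames(m) else
      rownames(m)[pooled_mean >= cfg$presence_floor]
  }
  in_uni <- rownames(m) %in% universe

  p <- rep(NA_real_, nrow(m))
  p[in_uni] <- ranksum_rows(m[in_uni, , drop = FALSE], tgt_ids, pooled_ids)
  q <- rep(NA_real_, nrow(m))
  q[in_uni] <- p.adjust(p[in_uni], method = "BH")

  label <- unname(ifelse(
    in_uni & len >= cfg$min_length & fold_eff > cfg$fold_threshold &
      !is.na(q) & q <= cfg$fdr_alpha,
    direction, "none"
  ))

  out <- tibble(peak_id = rownames(m), length = unname(len),
                mean_target = unname(tgt_mean))
  for (sp in comparison_species) {
    out[[paste0("mean_", sp)]] <- unname(comp_means[[sp]])
    out[[paste0("fold_", sp)]] <- unname(folds[[sp]])
  }
  out$mean_pooled <- unname(pooled_mean)
  out$fold_pooled <- unname(fold_pooled)
  out$fold <- unname(fold_eff)
  out$in_universe <- in_uni
  out$p <- unname(p)
  out$q <- unname(q)
  out$label <- label
  attr(out, "cfg") <- cfg
  attr(out, "direction") <- direction
  out
}

#' Call peaks with species-specific gain
#'
#' A peak is labeled `gain` when (i) it is at least `min_length` bp long,
#' (ii) the target-species mean density exceeds `fold_threshold` times the
#' comparison mean(s) (per `fold_mode`, with the pseudo-density added to
#' both sides), and (iii) the two-sided rank-sum test of target vs pooled
#' comparison samples survives BH FDR at `fdr_alpha` over all tested peaks.
#'
#' @param density Wide density tibble (ppm/kb).
#' @param samples Sample metadata tibble.
#' @param peaks Peak tibble (lengths).
#' @param target_species Species gaining the mark (e.g. `"human"`).
#' @param comparison_species Character vector of comparison species.
#' @param cfg An [analysis_config()].
#' @param cell_type Cell type whose samples enter the comparison.
#' @param universe Optional explicit candidate peak-id universe; defaults to
#'   all matrix peaks.
#' @return Call tibble: per-peak group means, folds, `p`, `q`, `label`.
#' @export
call_gain <- function(density, samples, peaks, target_species,
                      comparison_species, cfg = analysis_config(),
                      cell_type = "NeuN+", universe = NULL) {
  call_engine(density, samples, peaks, target_species, comparison_species,
              cfg, "gain", cell_type, universe)
}

#' Call peaks with species-specific depletion
#'
#' The reciprocal of [call_gain()]: peaks are first required to be
#' "detected" in the comparison species (pooled comparison mean at or above
#' `presence_floor`), then labeled `loss` when the comparison-over-target
#' fold clears the threshold with BH-adjusted rank-sum significance.
#'
#' @inheritParams call_gain
#' @return Call tibble with `label` in `{loss, none}`.
#' @export
call_depletion <- function(density, samples, peaks, target_species,
                           comparison_species, cfg = analysis_config(),
                           cell_type = "NeuN+", universe = NULL) {
  call_engine(density, samples, peaks, target_species, comparison_species,
              cfg, "loss", cell_type, universe)
}

#' Restrict calls to those enriched in neuronal over reference chromatin
#'
#' Keeps calls whose neuronal (NeuN+) mean density in the target species
#' exceeds `fold_threshold` times the mean of each reference cell type
#' (pseudo-density added), with BH-adjusted rank-sum significance of the
#' NeuN+ vs NeuN- comparison over the input call list.
#'
#' @param calls Call tibble (typically labeled rows of [call_gain()]).
#' @param density Wide density tibble including reference-cell-type samples.
#' @param samples Sample metadata tibble.
#' @param cfg An [analysis_config()].
#' @param target_species Species whose samples are compared across cell types.
#' @param neuronal_cell_type Cell type that must be enriched (`"NeuN+"`).
#' @param reference_cell_types Cell types the neuronal signal must exceed.
#' @return The subset of `calls` passing, with `neu_mean`, per-reference
#'   means/folds, `p_celltype` and `q_celltype` columns added.
#' @export
filter_celltype_enriched <- function(calls, density, samples,
                                     cfg = analysis_config(),
                                     target_species = "human",
                                     neuronal_cell_type = "NeuN+",
                                     reference_cell_types = "NeuN-") {
  if (nrow(calls) == 0) return(calls)
  samples <- validate_samples(samples)
  m <- matrix_from_tbl(density)
  m <- m[calls$peak_id, , drop = FALSE]
  eps <- cfg$pseudo_density
  sub <- samples[samples$species == target_species, ]
  neu_ids <- sub$sample_id[sub$cell_type == neuronal_cell_type]
  neu_ids <- intersect(neu_ids, colnames(m))
  if (length(neu_ids) < 2) abort("need >= 2 neuronal samples")
  neu_mean <- group_means(m, neu_ids)
  out <- calls
  out$neu_mean <- unname(neu_mean)
  pass_fold <- rep(TRUE, nrow(calls))
  for (ct in reference_cell_types) {
    ref_ids <- intersect(sub$sample_id[sub$cell_type == ct], colnames(m))
    if (!length(ref_ids)) {
      abort(sprintf("reference cell type '%s' absent from samples", ct))
    }
    ref_mean <- group_means(m, ref_ids)
    fold <- (neu_mean + eps) / (ref_mean + eps)
    key <- gsub("[^A-Za-z0-9]+", "_", ct)
    out[[paste0("mean_", key)]] <- unname(ref_mean)
    out[[paste0("fold_", key)]] <- unname(fold)
    pass_fold <- pass_fold & fold > cfg$fold_threshold
  }
  ref_test_ids <- intersect(sub$sample_id[sub$cell_type == "NeuN-"], colnames(m))
  if (length(ref_test_ids) < 2) abort("need >= 2 NeuN- samples for the test")
  out$p_celltype <- ranksum_rows(m, neu_ids, ref_test_ids)
  out$q_celltype <- p.adjust(out$p_celltype, method = "BH")
  out[pass_fold & out$q_celltype <= cfg$fdr_alpha, , drop = FALSE]
}

#' Intersect two call sets
#'
#' @param calls_a,calls_b Character vectors of peak ids, or call tibbles
#'   (their labeled rows' `peak_id`s are used).
#' @return One-row tibble `n_a`, `n_b`, `n_overlap`, `jaccard`.
#' @examples
#' intersect_calls(c("A", "B", "C"), c("B", "C", "D"))  # overlap 2, Jaccard 0.5
#' @export
intersect_calls <- function(calls_a, calls_b) {
  as_ids <- function(x) {
    if (is.data.frame(x)) x <- x$peak_id[x$label != "none"]
    unique(as.character(x))
  }
  a <- as_ids(calls_a); b <- as_ids(calls_b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  tibble(n_a = length(a), n_b = length(b), n_overlap = inter,
         jaccard = if (uni == 0) NA_real_ else inter / uni)
}

#' Select control peaks with minimal cross-species differences
#'
#' Ranks peaks by the maximum absolute log2 fold between any pair of
#' species group means (pseudo-density added) and returns the `k` least
#' divergent, optionally restricted to peaks whose length lies within
#' `length_window` bp of some member of a target peak set.
#'
#' @param density Wide density tibble.
#' @param samples Sample metadata tibble.
#' @param peaks Peak tibble.
#' @param k Number of control peaks to return.
#' @param cfg An [analysis_config()] (for the pseudo-density).
#' @param cell_type Cell type whose samples define the group means.
#' @param target_set Optional peak ids to length-match against.
#' @param length_window Half-width (bp) of the length-matching window.
#' @return Tibble `peak_id`, `length`, `score` (max |log2 fold|), `k` rows,
#'   most conserved first.
#' @export
select_control_peaks <- function(density, samples, peaks, k,
                                 cfg = analysis_config(),
                                 cell_type = "NeuN+",
                                 target_set = NULL, length_window = NULL) {
  samples <- validate_samples(samples)
  m <- matrix_from_tbl(density)
  eps <- cfg$pseudo_density
  use <- samples[samples$cell_type == cell_type, ]
  sp_means <- lapply(split(use$sample_id, use$species), function(ids) {
    ids <- intersect(ids, colnames(m))
    if (length(ids)) group_means(m, ids) else NULL
  })
  sp_means <- sp_means[!vapply(sp_means, is.null, logical(1))]
  if (length(sp_means) < 2) abort("need group means for >= 2 species")
  score <- rep(0, nrow(m))
  nm <- names(sp_means)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      lf <- abs(log2((sp_means[[i]] + eps) / (sp_means[[j]] + eps)))
      score <- pmax(score, lf)
    }
  }
  len <- setNames(peaks$length, peaks$peak_id)[rownames(m)]
  eligible <- rep(TRUE, nrow(m))
  if (!is.null(target_set) && !is.null(length_window)) {
    tlen <- len[intersect(target_set, names(len))]
    if (!length(tlen)) abort("target_set has no peaks in the matrix")
    eligible <- vapply(len, function(l) min(abs(l - tlen)) <= length_window,
                       logical(1))
  }
  pool <- tibble(peak_id = rownames(m), length = unname(len),
                 score = unname(score))[eligible, ]
  if (k > nrow(pool)) abort("k exceeds the eligible peak pool")
  pool[order(pool$score, pool$peak_id)[seq_len(k)], ]
}
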