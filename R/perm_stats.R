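# Resampling null machinery for interval statistics. The null model draws
# peak identities uniformly without replacement from the full atlas, so the
# atlas's chromosomal and positional structure is preserved exactly —
# intervals are never re-placed on the genome.

#' Count peaks with a close neighbor on the same chromosome
#'
#' Number of peaks in the set that have at least one other member within
#' `d` bp on the same chromosome. Distances are midpoint-to-midpoint by
#' default (robust to unequal peak lengths); `anchor = "edge"` uses the
#' gap between interval edges instead. `count = "pairs"` counts qualifying
#' pairs rather than peaks.
#'
#' @param peaks Peak tibble.
#' @param d Distance threshold in bp (exclusive: strictly less than `d`).
#' @param anchor `"midpoint"` or `"edge"`.
#' @param count `"peaks"` (default) or `"pairs"`.
#' @return Integer count.
#' @examples
#' layout <- genome_layout("chr1", 5e6)
#' pk <- validate_peaks(tibble::tibble(
#'   peak_id = c("a", "b", "c"), chrom = "chr1",
#'   start = c(99500, 699500, 1999500), end = c(100500, 700500, 2000500)),
#'   layout)
#' pairing_count(pk, 1e6)  # a and b pair; c's nearest neighbor is 1.3 Mb off
#' @export
pairing_count <- function(peaks, d, anchor = c("midpoint", "edge"),
                          count = c("peaks", "pairs")) {
  anchor <- match.arg(anchor)
  count <- match.arg(count)
  stopifnot(d > 0)
  n <- nrow(peaks)
  if (n < 2) return(0L)
  if (anchor == "midpoint") {
    pos <- (peaks$start + peaks$end) / 2
    lo <- pos; hi <- pos
  } else {
    lo <- peaks$start; hi <- peaks$end
  }
  total <- 0L
  for (idx in split(seq_len(n), peaks$chrom)) {
    if (length(idx) < 2) next
    o <- idx[order(lo[idx])]
    gap <- lo[o[-1]] - hi[o[-length(o)]]  # distance to previous neighbor
    near <- gap < d
    if (count == "pairs") {
      # neighbors beyond adjacency: count all pairs within d (edge gaps are
      # monotone in sorted order only for midpoint anchor, so do it directly)
      p <- lo[o]; q <- hi[o]
      cnt <- 0L
      for (i in seq_along(o)) {
        j <- i + 1L
        while (j <= length(o) && p[j] - q[i] < d) {
          cnt <- cnt + 1L
          j <- j + 1L
        }
      }
      total <- total + cnt
    } else {
      has <- c(near, FALSE) | c(FALSE, near)
      total <- total + sum(has)
    }
  }
  as.integer(total)
}

# TRUE for each peak overlapping (>= 1 bp) any interval of the annotation.
annot_membership <- function(peaks, annot) {
  hit <- logical(nrow(peaks))
  if (is.null(annot) || nrow(annot) == 0 || nrow(peaks) == 0) return(hit)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ai <- which(annot$chrom == ch)
    if (!length(ai)) next
    pr <- IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi])
    ar <- IRanges::IRanges(annot$start[ai] + 1L, annot$end[ai])
    hit[pi] <- IRanges::overlapsAny(pr, ar)
  }
  hit
}

#' Assign each peak to an annotation-overlap category
#'
#' A peak is "in" an annotation iff it overlaps at least 1 bp of any of its
#' intervals (no reciprocal-fraction requirement). Categories:
#' `both`, `target_only`, `other_only`, `neither`.
#'
#' @param peaks Peak tibble.
#' @param annot_target,annot_other Annotation tibbles (`chrom,start,end`).
#' @return `peaks` with logical `in_target`, `in_other` and a `category`
#'   column.
#' @export
categorize_peaks <- function(peaks, annot_target, annot_other) {
  in_t <- annot_membership(peaks, annot_target)
  in_o <- annot_membership(peaks, annot_other)
  mutate(as_tibble(peaks), in_target = in_t, in_other = in_o,
         category = dplyr::case_when(
           in_t & in_o ~ "both",
           in_t ~ "target_only",
           in_o ~ "other_only",
           TRUE ~ "neither"
         ))
}

.categories <- c("both", "target_only", "other_only", "neither")

#' Overlap category counts for a peak set
#'
#' @inheritParams categorize_peaks
#' @return Tibble `category`, `n`; counts sum to `nrow(peaks)`.
#' @export
overlap_categories <- function(peaks, annot_target, annot_other) {
  cat <- categorize_peaks(peaks, annot_target, annot_other)$category
  tibble(category = .categories,
         n = as.integer(table(factor(cat, levels = .categories))))
}

#' Resampling null for a peak-set statistic
#'
#' Draws `n_sims` subsets of `subset_size` peaks uniformly without
#' replacement from the pool, evaluates the statistic on each, and reports
#' the add-one empirical p of the observed value in the requested
#' direction: `p = (1 + #{null >= observed}) / (1 + n_sims)` for
#' `direction = "greater"` (`<=` for `"less"`). The statistic may return a
#' named vector; each component then gets its own row.
#'
#' @param pool Full peak atlas tibble (may carry precomputed columns for the
#'   statistic to use).
#' @param subset_size Size of each resampled subset.
#' @param statistic Function of a peak tibble returning a (named) numeric.
#' @param observed Observed statistic value(s) on the real subset, matching
#'   the statistic's output.
#' @param n_sims Number of resamples (>= 1).
#' @param seed RNG seed; identical seed + inputs give identical results.
#' @param direction `"greater"` or `"less"`, recycled across components.
#' @return A `perm_result` tibble: one row per statistic component with
#'   `observed`, `null_mean`, `null_sd`, `fold_enrichment`, `p`,
#'   `direction`, `n_sims`, `seed`.
#' @export
resample_null <- function(pool, subset_size, statistic, observed,
                          n_sims = 10000, seed = 1L,
                          direction = "greater") {
  if (subset_size > nrow(pool)) abort("subset_size exceeds the pool")
  if (n_sims < 1) abort("n_sims must be >= 1")
  if (!all(direction %in% c("greater", "less"))) {
    abort("direction must be 'greater' or 'less'")
  }
  observed <- unlist(observed)
  k <- length(observed)
  direction <- rep_len(direction, k)
  null <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      idx <- sample.int(nrow(pool), subset_size)
      unlist(statistic(pool[idx, , drop = FALSE]))
    }, numeric(k))
  })
  null <- matrix(null, nrow = k)
  nm <- names(observed) %||% paste0("stat_", seq_len(k))
  exceed <- vapply(seq_len(k), function(j) {
    if (direction[j] == "greater") sum(null[j, ] >= observed[j])
    else sum(null[j, ] <= observed[j])
  }, numeric(1))
  null_mean <- rowMeans(null)
  out <- tibble(
    statistic = nm,
    observed = unname(observed),
    null_mean = null_mean,
    null_sd = apply(null, 1, sd),
    fold_enrichment = ifelse(null_mean > 0, unname(observed) / null_mean,
                             NA_real_),
    p = (1 + exceed) / (1 + n_sims),
    direction = direction,
    n_sims = as.integer(n_sims),
    seed = as.integer(seed)
  )
  class(out) <- c("perm_result", class(out))
  out
}

#' Enrichment test of a peak subset against the atlas null
#'
#' Wraps [resample_null()] with the pairing-within-distance statistic
#' (`mode = "clustering"`) or the four annotation-overlap category counts
#' (`mode = "overlap"`).
#'
#' @param subset Peak tibble: the subset under test (must be drawn from the
#'   pool's peak universe).
#' @param pool Full peak atlas tibble.
#' @param mode `"clustering"` or `"overlap"`.
#' @param d Pairing distance (bp), clustering mode.
#' @param annot_target,annot_other Annotation tibbles, overlap mode.
#' @param n_sims,seed Passed to [resample_null()].
#' @param direction Test direction(s); recycled over the four categories in
#'   overlap mode.
#' @param anchor,count Passed to [pairing_count()].
#' @return A `perm_result` tibble (one row for clustering; one per category
#'   for overlap).
#' @export
enrichment_test <- function(subset, pool, mode = c("clustering", "overlap"),
                            d = 1e6, annot_target = NULL, annot_other = NULL,
                            n_sims = 10000, seed = 1L, direction = "greater",
                            anchor = "midpoint", count = "peaks") {
  mode <- match.arg(mode)
  if (!all(subset$peak_id %in% pool$peak_id)) {
    abort("subset contains peaks outside the pool")
  }
  if (mode == "clustering") {
    stat <- function(p) c(paired_peaks = pairing_count(p, d, anchor, count))
    obs <- stat(subset)
  } else {
    if (is.null(annot_target) || is.null(annot_other)) {
      abort("overlap mode needs both annotation sets")
    }
    # categorize the pool once; resamples just tabulate the stored category
    pool <- categorize_peaks(pool, annot_target, annot_other)
    stat <- function(p) {
      setNames(as.integer(table(factor(p$category, levels = .categories))),
               .categories)
    }
    obs <- stat(pool[match(subset$peak_id, pool$peak_id), , drop = FALSE])
  }
  resample_null(pool, nrow(subset), stat, obs, n_sims = n_sims, seed = seed,
                direction = direction)
}

#' @export
tidy.perm_result <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.perm_result <- function(x, ...) {
  tibble(n_statistics = nrow(x), n_sims = x$n_sims[1], seed = x$seed[1],
         min_p = min(x$p))
}

#' Observed vs expected bar chart for a permutation result
#'
#' @param object A `perm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(unclass(object))[, c("statistic", "observed", "null_mean")],
    c("observed", "null_mean"), names_to = "which", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$statistic, .data$value,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(null_mean = "steelblue",
                                          observed = "firebrick"),
                               labels = c(null_mean = "expected",
                                          observed = "observed")) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
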