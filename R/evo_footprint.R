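# Human-specific sequence alterations (HSAs) in per-peak multi-taxon
# alignment blocks: substitution/indel event calling by comparison-taxon
# unanimity (parsimony), archaic-hominin allele partitioning, per-kb rate
# comparison between peak groups, and IUPAC consensus motif gain/loss.

.iupac_letters <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

# split one block (long tibble rows for a peak) into a taxon-named list of
# character vectors
block_chars <- function(block) {
  setNames(strsplit(block$seq, "", fixed = TRUE), block$taxon)
}

count_hsas_block <- function(block, comparison_taxa, archaic_taxa) {
  ch <- block_chars(block)
  missing <- setdiff(c("human", comparison_taxa), names(ch))
  if (length(missing)) {
    abort(sprintf("block '%s' lacks taxon '%s'", block$peak_id[1], missing[1]))
  }
  hum <- ch[["human"]]
  comp <- do.call(rbind, ch[comparison_taxa])
  nc <- length(hum)
  base <- c("A", "C", "G", "T")

  comp_is_base <- matrix(comp %in% base, nrow = nrow(comp))
  comp_all_base <- colSums(comp_is_base) == nrow(comp)
  comp_all_gap <- colSums(comp == "-") == nrow(comp)
  comp_agree <- colSums(comp == rep(comp[1, ], each = nrow(comp))) == nrow(comp)
  hum_is_base <- hum %in% base
  out_allele <- comp[1, ]

  is_sub <- hum_is_base & comp_all_base & comp_agree & hum != out_allele
  is_del <- hum == "-" & comp_all_base & comp_agree
  is_ins <- hum_is_base & comp_all_gap

  arc_present <- intersect(archaic_taxa, names(ch))
  arc_state <- function(cols, human_str, out_str) {
    vapply(archaic_taxa, function(tx) {
      if (!tx %in% arc_present) return("missing")
      a <- paste(ch[[tx]][cols], collapse = "")
      if (a == human_str) "derived"
      else if (a == out_str) "ancestral"
      else "missing"
    }, character(1))
  }

  rows <- list()
  emit <- function(col0, kind, len, human_str, out_str) {
    kind_out <- if (kind != "substitution" && len >= 100) "long_indel" else kind
    states <- arc_state(seq.int(col0 + 1L, col0 + len), human_str, out_str)
    rec <- tibble(peak_id = block$peak_id[1], column = col0, kind = kind_out,
                  length = as.integer(len), human_allele = human_str,
                  outgroup_allele = out_str)
    for (tx in archaic_taxa) rec[[paste0("state_", tx)]] <- states[[tx]]
    rows[[length(rows) + 1L]] <<- rec
  }

  for (i in which(is_sub)) {
    emit(i - 1L, "substitution", 1L, hum[i], out_allele[i])
  }
  run_events <- function(flag, kind) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      cols <- seq.int(starts[j], ends[j])
      emit(starts[j] - 1L, kind, length(cols),
           paste(hum[cols], collapse = ""),
           paste(out_allele[cols], collapse = ""))
    }
  }
  run_events(is_del, "deletion")
  run_events(is_ins, "insertion")

  if (!length(rows)) {
    rec <- tibble(peak_id = character(), column = integer(), kind = character(),
                  length = integer(), human_allele = character(),
                  outgroup_allele = character())
    for (tx in archaic_taxa) rec[[paste0("state_", tx)]] <- character()
    return(rec)
  }
  arrange(bind_rows(rows), .data$column)
}

#' Count human-specific sequence alterations in alignment blocks
#'
#' A column is a substitution HSA iff every comparison taxon carries one
#' identical non-gap, non-N base differing from the human base (columns
#' with N anywhere, or disagreement among comparison taxa, are
#' uninformative under parsimony and skipped). Maximal runs of human-gap
#' columns (deletions) or all-comparison-gap columns (insertions) where
#' the comparison taxa agree form one indel event each; events of 100 bp or
#' more are labeled `long_indel`. Archaic rows never create or destroy
#' HSAs — they only annotate each event with `derived` (archaic equals the
#' human allele), `ancestral` (equals the outgroup allele) or `missing`.
#'
#' @param blocks Long alignment tibble (`peak_id`, `taxon`, `seq`).
#' @param comparison_taxa Taxa whose unanimous state defines the outgroup
#'   allele (e.g. chimpanzee, gorilla, orangutan, macaque).
#' @param archaic_taxa Optional archaic-hominin taxa to annotate.
#' @return Tibble of HSA events: `peak_id`, `column` (0-based alignment
#'   column), `kind`, `length`, `human_allele`, `outgroup_allele`, and one
#'   `state_<taxon>` column per archaic taxon.
#' @export
count_hsas <- function(blocks, comparison_taxa,
                       archaic_taxa = character()) {
  blocks <- as_tibble(blocks)
  purrr::map_dfr(split(blocks, factor(blocks$peak_id,
                                      levels = unique(blocks$peak_id))),
                 count_hsas_block, comparison_taxa = comparison_taxa,
                 archaic_taxa = archaic_taxa)
}

#' Fraction of HSAs postdating the split from an archaic lineage
#'
#' An HSA is "post-split" iff the archaic genome carries the ancestral
#' (outgroup) allele. The fraction is taken over HSAs with a non-missing
#' state for the taxon.
#'
#' @param hsas HSA tibble from [count_hsas()].
#' @param taxon Archaic taxon name (a `state_<taxon>` column must exist).
#' @return Fraction in `[0, 1]`.
#' @export
archaic_fraction <- function(hsas, taxon) {
  col <- paste0("state_", taxon)
  if (!col %in% names(hsas)) abort(sprintf("no archaic states for '%s'", taxon))
  st <- hsas[[col]]
  st <- st[st != "missing"]
  if (!length(st)) abort(sprintf("all archaic states missing for '%s'", taxon))
  sum(st == "ancestral") / length(st)
}

#' Per-peak HSA rates
#'
#' Events per kb of ungapped human sequence, for every peak present in the
#' alignment blocks (peaks without events get rate 0).
#'
#' @param hsas HSA tibble from [count_hsas()].
#' @param blocks The alignment tibble the events were called from.
#' @return Tibble `peak_id`, `n_hsa`, `human_bp` (ungapped), `rate`
#'   (HSAs per kb).
#' @export
hsa_rates <- function(hsas, blocks) {
  hum <- blocks[blocks$taxon == "human", c("peak_id", "seq")]
  hum$human_bp <- nchar(gsub("-", "", hum$seq, fixed = TRUE))
  if (any(hum$human_bp == 0)) {
    abort(sprintf("zero-length human sequence in block '%s'",
                  hum$peak_id[hum$human_bp == 0][1]))
  }
  counts <- hsas |> group_by(.data$peak_id) |>
    summarise(n_hsa = n(), .groups = "drop")
  hum |>
    left_join(counts, by = "peak_id") |>
    mutate(n_hsa = dplyr::coalesce(.data$n_hsa, 0L),
           rate = .data$n_hsa / (.data$human_bp / 1000)) |>
    select("peak_id", "n_hsa", "human_bp", "rate")
}

#' Compare per-peak HSA rates between two peak groups
#'
#' Two-sided Wilcoxon rank-sum test (exact when the smaller group has at
#' most 12 members and there are no ties, else normal approximation with
#' continuity correction) plus a label-permutation test on the absolute
#' difference of group means with the add-one empirical p estimator.
#'
#' @param rates_a,rates_b Numeric rate vectors, or tibbles with a `rate`
#'   column (e.g. from [hsa_rates()]).
#' @param n_sims Number of label permutations.
#' @param seed RNG seed.
#' @return A `group_comparison` object; see [tidy()] and [glance()].
#' @export
compare_groups <- function(rates_a, rates_b, n_sims = 10000, seed = 1L) {
  if (is.data.frame(rates_a)) rates_a <- rates_a$rate
  if (is.data.frame(rates_b)) rates_b <- rates_b$rate
  if (!length(rates_a) || !length(rates_b)) abort("both groups must be non-empty")
  if (n_sims < 1) abort("n_sims must be >= 1")
  exact <- min(length(rates_a), length(rates_b)) <= 12
  w <- suppressWarnings(
    wilcox.test(rates_a, rates_b, exact = exact, correct = TRUE))
  obs <- abs(mean(rates_a) - mean(rates_b))
  all_r <- c(rates_a, rates_b)
  na <- length(rates_a)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_sims), function(i) {
      idx <- sample.int(length(all_r), na)
      abs(mean(all_r[idx]) - mean(all_r[-idx])) >= obs
    }, logical(1)))
  })
  structure(list(
    rates_a = rates_a, rates_b = rates_b,
    mean_a = mean(rates_a), sd_a = sd(rates_a),
    mean_b = mean(rates_b), sd_b = sd(rates_b),
    wilcox_p = w$p.value,
    perm_p = (1 + exceed) / (1 + n_sims),
    n_sims = as.integer(n_sims), seed = as.integer(seed)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group A: %.2f +/- %.2f (n = %d)\ngroup B: %.2f +/- %.2f (n = %d)\n",
    x$mean_a, x$sd_a, length(x$rates_a),
    x$mean_b, x$sd_b, length(x$rates_b)))
  cat(sprintf("Wilcoxon rank-sum p = %.3g; permutation p = %.3g (%d sims)\n",
              x$wilcox_p, x$perm_p, x$n_sims))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(group = c("a", "b"),
         n = c(length(x$rates_a), length(x$rates_b)),
         mean = c(x$mean_a, x$mean_b),
         sd = c(x$sd_a, x$sd_b))
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(mean_a = x$mean_a, mean_b = x$mean_b,
         wilcox_p = x$wilcox_p, perm_p = x$perm_p,
         n_sims = x$n_sims, seed = x$seed)
}

#' Rate distributions of the two compared groups
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble(
    group = rep(c("a", "b"), c(length(object$rates_a), length(object$rates_b))),
    rate = c(object$rates_a, object$rates_b))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "HSAs per kb") +
    ggplot2::theme_minimal()
}

#' Scan a sequence for an IUPAC consensus motif on both strands
#'
#' Reports every forward-strand match of the degenerate pattern and every
#' match of its reverse complement (strand `-`, position given as the
#' forward-strand start of the matched window). Positions are 0-based. An
#' `N` in the sequence never satisfies a non-`N` pattern letter; a pattern
#' `N` matches any base.
#'
#' @param sequence Character scalar over `A,C,G,T,N` (strip gaps first).
#' @param pattern IUPAC consensus string (e.g. `"WGATTAG"` for GATA-1).
#' @return Tibble `position` (0-based), `strand` (`+`/`-`).
#' @examples
#' scan_motif("CCTGATTAGCC", "WGATTAG")
#' @export
scan_motif <- function(sequence, pattern) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern) ||
      grepl(sprintf("[^%s]", paste(.iupac_letters, collapse = "")), pattern)) {
    abort("pattern must be a non-empty IUPAC string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(pattern)) {
    return(tibble(position = integer(), strand = character()))
  }
  subj <- Biostrings::DNAString(sequence)
  hit <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    Biostrings::start(m) - 1L
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  out <- bind_rows(
    tibble(position = hit(pattern), strand = "+"),
    tibble(position = hit(rc), strand = "-")
  )
  arrange(out, .data$position, .data$strand)
}

# ungapped-position -> alignment-column map (0-based columns) and matches
# (with column windows) for one taxon's row
taxon_matches <- function(seq, pattern) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cols <- which(chars != "-") - 1L          # column of each ungapped base
  ungapped <- paste(chars[chars != "-"], collapse = "")
  hits <- scan_motif(ungapped, pattern)
  k <- nchar(pattern)
  if (nrow(hits)) {
    hits$col_start <- cols[hits$position + 1L]
    hits$col_end <- cols[hits$position + k]
  } else {
    hits$col_start <- integer()
    hits$col_end <- integer()
  }
  hits
}

windows_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

any_overlapping_match <- function(hits, cs, ce) {
  nrow(hits) > 0 && any(windows_overlap(hits$col_start, hits$col_end, cs, ce))
}

motif_events_block <- function(block, pattern, comparison_taxa) {
  ch <- setNames(block$seq, block$taxon)
  missing <- setdiff(c("human", comparison_taxa), names(ch))
  if (length(missing)) {
    abort(sprintf("block '%s' lacks taxon '%s'", block$peak_id[1], missing[1]))
  }
  hum_hits <- taxon_matches(ch[["human"]], pattern)
  comp_hits <- lapply(ch[comparison_taxa], taxon_matches, pattern = pattern)

  events <- list()
  # gained: human match with no comparison-taxon match in the orthologous
  # (column) window
  for (i in seq_len(nrow(hum_hits))) {
    cs <- hum_hits$col_start[i]; ce <- hum_hits$col_end[i]
    if (!any(vapply(comp_hits, any_overlapping_match, logical(1), cs, ce))) {
      events[[length(events) + 1L]] <- tibble(
        peak_id = block$peak_id[1], column = cs,
        strand = hum_hits$strand[i], kind = "gained")
    }
  }
  # lost: match shared by all comparison taxa (overlapping windows) with no
  # human match in the window
  ref <- comp_hits[[1]]
  for (i in seq_len(nrow(ref))) {
    cs <- ref$col_start[i]; ce <- ref$col_end[i]
    shared <- all(vapply(comp_hits[-1], any_overlapping_match, logical(1),
                         cs, ce))
    if (shared && !any_overlapping_match(hum_hits, cs, ce)) {
      events[[length(events) + 1L]] <- tibble(
        peak_id = block$peak_id[1], column = cs,
        strand = ref$strand[i], kind = "lost")
    }
  }
  if (!length(events)) {
    return(tibble(peak_id = character(), column = integer(),
                  strand = character(), kind = character()))
  }
  arrange(bind_rows(events), .data$column)
}

#' Compare motif-event tallies between two peak groups
#'
#' 2x2 test of event counts (e.g. lost-motif events out of all events) in
#' two groups. Because the standard chi-square has two common variants,
#' both Pearson and the Yates continuity-corrected p are reported, plus
#' Fisher's exact p.
#'
#' @param k_a,n_a Events and totals in group A.
#' @param k_b,n_b Events and totals in group B.
#' @return One-row tibble with the proportions and the three p-values.
#' @export
motif_tally_test <- function(k_a, n_a, k_b, n_b) {
  m <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2)
  tibble(
    prop_a = k_a / n_a, prop_b = k_b / n_b,
    pearson_p = suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
    yates_p = suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value),
    fisher_p = stats::fisher.test(m)$p.value
  )
}

#' Motif gains and losses on the human lineage
#'
#' A `gained` event is a motif match in the human ungapped sequence whose
#' aligned (orthologous) column window contains no match in any comparison
#' taxon; a `lost` event is a match shared by all comparison taxa with no
#' human match in the window. Orthology is resolved through alignment
#' columns, not genome coordinates.
#'
#' @param blocks Long alignment tibble.
#' @param pattern IUPAC consensus string.
#' @param comparison_taxa Comparison taxon names.
#' @return Tibble `peak_id`, `column` (0-based start), `strand`, `kind`.
#' @export
motif_events <- function(blocks, pattern, comparison_taxa) {
  blocks <- as_tibble(blocks)
  purrr::map_dfr(split(blocks, factor(blocks$peak_id,
                                      levels = unique(blocks$peak_id))),
                 motif_events_block, pattern = pattern,
                 comparison_taxa = comparison_taxa)
}
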