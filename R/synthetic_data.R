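# Synthetic-data generators with planted ground truth. The defaults
# emulate the study conditions every stage is scored against: an atlas of
# thousands of >=500 bp peaks, 11 human + 4 chimpanzee + 3 macaque neuronal
# ChIP-seq samples with overdispersed (negative-binomial) counts and
# log-normal peak strengths, sperm-hypomethylome-like annotation tracks
# with a 5.7% baseline / 22% enriched target-only fraction, and 1-kb
# five-primate alignment blocks with an elevated human-branch alteration
# rate (around 20 events/kb in the enriched group vs around 8 in controls)
# and archaic genomes carrying the ancestral allele at a configurable
# post-split fraction.

#' Generator specification
#'
#' All knobs of the synthetic cohort, with defaults matching the study
#' conditions the pipeline is scored under.
#'
#' @param layout Genome layout to place peaks on.
#' @param n_peaks Pool size.
#' @param peak_length_range Min/max peak length (bp).
#' @param n_human,n_chimp,n_macaque NeuN+ samples per species (humans split
#'   7 children / 4 adults by default).
#' @param n_human_neun_neg Human NeuN- (non-neuronal) samples.
#' @param library_size_range Range of total mapped tags per sample.
#' @param baseline_meanlog,baseline_sdlog Log-normal peak strength
#'   (expected density, ppm/kb).
#' @param dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @param n_gain,gain_fold,gain_species,gain_cell_type Planted gain set.
#' @param effect_sd,within_cor,cross_cor Optional log-scale per-sample
#'   effect with species-level correlation structure (off when
#'   `effect_sd = 0`).
#' @param annotation_fractions Baseline category probabilities
#'   (both / target_only / other_only / neither), summing to 1.
#' @param enriched_target_only Target-only probability for the planted
#'   (enriched) subset.
#' @param n_clustered Peaks placed as close pairs (even number).
#' @param cluster_pair_distance Maximum midpoint distance within a planted
#'   pair (bp).
#' @param block_length Alignment block length (bp of ancestral sequence).
#' @param rate_human Human-branch substitutions per kb.
#' @param rate_comparison Per-comparison-taxon substitutions per kb.
#' @param indel_rate_human Human-branch short indels (1-10 bp) per kb.
#' @param long_indel_rate_human Human-branch long indels (100-300 bp) per kb.
#' @param comparison_taxa,archaic_taxa Taxon names for alignment blocks.
#' @param archaic_post_split Probability an archaic genome carries the
#'   ancestral allele at a planted human alteration.
#' @param rng_seed Default seed for the generators.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(layout = genome_layout(paste0("chr", 1:10),
                                                  rep(3e7, 10), "synth1"),
                           n_peaks = 2000,
                           peak_length_range = c(500, 5000),
                           n_human = 11, n_chimp = 4, n_macaque = 3,
                           n_human_neun_neg = 4,
                           library_size_range = c(8e6, 1.5e7),
                           baseline_meanlog = log(4), baseline_sdlog = 0.75,
                           dispersion = 0.2,
                           n_gain = min(100, n_peaks), gain_fold = 4,
                           gain_species = "human", gain_cell_type = "NeuN+",
                           effect_sd = 0, within_cor = 0.9, cross_cor = 0.5,
                           annotation_fractions = c(both = 0.73,
                                                    target_only = 0.057,
                                                    other_only = 0.005,
                                                    neither = 0.208),
                           enriched_target_only = 0.22,
                           n_clustered = 0, cluster_pair_distance = 4e5,
                           block_length = 1000,
                           rate_human = 20, rate_comparison = 5,
                           indel_rate_human = 0.5,
                           long_indel_rate_human = 0.02,
                           comparison_taxa = c("chimpanzee", "gorilla",
                                               "orangutan", "macaque"),
                           archaic_taxa = c("neanderthal", "denisova"),
                           archaic_post_split = 0.3,
                           rng_seed = 1L) {
  stopifnot(n_peaks >= 0, peak_length_range[1] >= 1,
            peak_length_range[2] >= peak_length_range[1],
            dispersion >= 0, gain_fold > 0, n_gain <= n_peaks,
            abs(sum(annotation_fractions) - 1) < 1e-8,
            enriched_target_only >= 0, enriched_target_only <= 1,
            n_clustered %% 2 == 0, rate_human >= 0, rate_comparison >= 0,
            archaic_post_split >= 0, archaic_post_split <= 1)
  structure(as.list(environment()), class = "generator_spec")
}

#' Default synthetic sample table
#'
#' Deterministic metadata for the synthetic cohort: NeuN+ samples for each
#' species (humans split child/adult), optional human NeuN- samples, and
#' library sizes spaced over `library_size_range`.
#'
#' @param spec A [generator_spec()].
#' @return Sample metadata tibble.
#' @export
gen_samples <- function(spec) {
  mk <- function(prefix, n, species, cell_type, ages) {
    if (n == 0) return(NULL)
    tibble(sample_id = paste0(prefix, seq_len(n)), species = species,
           cell_type = cell_type,
           library_size = round(seq(spec$library_size_range[1],
                                    spec$library_size_range[2],
                                    length.out = n)),
           age_group = ages)
  }
  n_child <- min(7, spec$n_human)
  validate_samples(bind_rows(
    mk("H", spec$n_human, "human", "NeuN+",
       rep(c("child", "adult"), c(n_child, spec$n_human - n_child))),
    mk("HN", spec$n_human_neun_neg, "human", "NeuN-", "adult"),
    mk("C", spec$n_chimp, "chimpanzee", "NeuN+", "adult"),
    mk("M", spec$n_macaque, "macaque", "NeuN+", "adult")
  ))
}

#' Generate a peak pool with optional planted clustering
#'
#' Peaks are placed disjointly (uniform placement of non-overlapping
#' intervals per chromosome, chromosomes drawn in proportion to length).
#' When `n_clustered > 0`, that many peaks are placed as consecutive pairs
#' whose midpoint distance is below `cluster_pair_distance` by
#' construction.
#'
#' @param spec A [generator_spec()].
#' @param seed RNG seed (default `spec$rng_seed`).
#' @return List with `peaks` (peak tibble) and `truth`
#'   (`peak_id`, `clustered`, `pair_id`).
#' @export
gen_peak_pool <- function(spec, seed = spec$rng_seed) {
  n <- spec$n_peaks
  if (n == 0) {
    empty <- tibble(peak_id = character(), chrom = character(),
                    start = double(), end = double(), length = double())
    return(list(peaks = empty,
                truth = tibble(peak_id = character(), clustered = logical(),
                               pair_id = integer())))
  }
  with_seed(seed, {
    len <- round(runif(n, spec$peak_length_range[1], spec$peak_length_range[2]))
    pair_id <- rep(NA_integer_, n)
    if (spec$n_clustered > 0) {
      pair_id[seq_len(spec$n_clustered)] <-
        rep(seq_len(spec$n_clustered / 2), each = 2)
    }
    # placement units: a pair is placed as one super-interval whose gap
    # keeps the midpoint distance under the configured threshold
    units <- list()
    i <- 1L
    while (i <= n) {
      if (!is.na(pair_id[i])) {
        max_gap <- spec$cluster_pair_distance - (len[i] + len[i + 1L]) / 2
        if (max_gap <= 1) abort("cluster_pair_distance too small for peak lengths")
        gap <- floor(runif(1, 0, max_gap))
        units[[length(units) + 1L]] <- list(idx = c(i, i + 1L), gap = gap)
        i <- i + 2L
      } else {
        units[[length(units) + 1L]] <- list(idx = i, gap = 0)
        i <- i + 1L
      }
    }
    unit_len <- vapply(units, function(u) sum(len[u$idx]) + u$gap, numeric(1))
    chrom_i <- sample.int(nrow(spec$layout), length(units), replace = TRUE,
                          prob = spec$layout$length)
    start <- end <- numeric(n)
    chrom <- character(n)
    for (ci in unique(chrom_i)) {
      ui <- which(chrom_i == ci)
      clen <- spec$layout$length[ci]
      free <- clen - sum(unit_len[ui])
      if (free < 0) abort("infeasible packing: peaks exceed chromosome length")
      offs <- sort(floor(runif(length(ui), 0, free)))
      pos <- offs + c(0, cumsum(unit_len[ui]))[seq_along(ui)]
      for (k in seq_along(ui)) {
        u <- units[[ui[k]]]
        s <- pos[k]
        for (j in u$idx) {
          chrom[j] <- spec$layout$chrom[ci]
          start[j] <- s
          end[j] <- s + len[j]
          s <- end[j] + u$gap
        }
      }
    }
    peaks <- validate_peaks(
      tibble(peak_id = sprintf("peak_%04d", seq_len(n)), chrom = chrom,
             start = start, end = end),
      spec$layout)
    list(peaks = peaks,
         truth = tibble(peak_id = peaks$peak_id,
                        clustered = !is.na(pair_id), pair_id = pair_id))
  })
}

#' Generate an overdispersed count matrix with planted species effects
#'
#' `count(p, s) ~ NB(mean = strength(p) x fold(p, s) x library_size(s)/1e6
#' x length(p)/1e3, dispersion)`, so the expected density of a peak equals
#' its log-normal strength (ppm/kb) times the planted fold. The planted
#' fold applies where the sample belongs to the affected species/cell type
#' and the peak to the planted set. With `effect_sd > 0` an additional
#' log-scale per-sample effect with species-level correlation structure
#' (`within_cor` within species, `cross_cor` across) multiplies the mean.
#'
#' @param peaks Peak tibble from [gen_peak_pool()].
#' @param spec A [generator_spec()].
#' @param samples Sample tibble (default [gen_samples()]).
#' @param seed RNG seed.
#' @param planted_ids Optional explicit planted peak ids (default: `n_gain`
#'   peaks drawn at random).
#' @return List with `counts` (wide tibble) and `truth`
#'   (`peak_id`, `strength`, `planted`, `fold`).
#' @export
gen_counts <- function(peaks, spec, samples = gen_samples(spec),
                       seed = spec$rng_seed, planted_ids = NULL) {
  n <- nrow(peaks)
  ns <- nrow(samples)
  with_seed(seed, {
    strength <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
    planted <- if (!is.null(planted_ids)) {
      peaks$peak_id %in% planted_ids
    } else {
      p <- rep(FALSE, n)
      if (spec$n_gain > 0) p[sample.int(n, spec$n_gain)] <- TRUE
      p
    }
    affected <- samples$species == spec$gain_species &
      samples$cell_type == spec$gain_cell_type
    fold <- matrix(1, n, ns)
    fold[planted, affected] <- spec$gain_fold
    mu <- outer(strength * peaks$length / 1e3, samples$library_size / 1e6) *
      fold
    if (spec$effect_sd > 0) {
      b <- spec$cross_cor / spec$within_cor
      shared <- stats::rnorm(n)
      sp <- unique(samples$species)
      z_sp <- sqrt(b) * shared +
        sqrt(1 - b) * matrix(stats::rnorm(n * length(sp)), n)
      colnames(z_sp) <- sp
      a <- spec$within_cor
      u <- sqrt(a) * z_sp[, samples$species, drop = FALSE] +
        sqrt(1 - a) * matrix(stats::rnorm(n * ns), n)
      mu <- mu * exp(spec$effect_sd * u)
    }
    cnt <- if (spec$dispersion > 0) {
      matrix(rnbinom(n * ns, mu = mu, size = 1 / spec$dispersion), n)
    } else {
      matrix(rpois(n * ns, mu), n)
    }
    colnames(cnt) <- samples$sample_id
    rownames(cnt) <- peaks$peak_id
    list(counts = tbl_from_matrix(cnt),
         truth = tibble(peak_id = peaks$peak_id, strength = strength,
                        planted = planted,
                        fold = ifelse(planted, spec$gain_fold, 1)))
  })
}

#' Generate annotation tracks with controllable overlap categories
#'
#' Each peak is assigned a category (`both`, `target_only`, `other_only`,
#' `neither`) with the baseline probabilities; peaks in `enriched_ids` use
#' `enriched_target_only` for the target-only category (the remaining mass
#' rescaled proportionally). Annotation intervals are carved strictly
#' inside the assigned peaks, so — peaks being disjoint — the realized
#' overlap category of every peak equals its truth-table category exactly.
#'
#' @param peaks Peak tibble (disjoint intervals, e.g. from
#'   [gen_peak_pool()]).
#' @param spec A [generator_spec()].
#' @param enriched_ids Peak ids forming the planted (enriched) subset.
#' @param seed RNG seed.
#' @return List with `target`, `other` (annotation tibbles) and `truth`
#'   (`peak_id`, `category`).
#' @export
gen_annotations <- function(peaks, spec, enriched_ids = character(),
                            seed = spec$rng_seed) {
  base_p <- spec$annotation_fractions[.categories]
  if (any(is.na(base_p)) || abs(sum(base_p) - 1) > 1e-8) {
    abort("annotation_fractions must cover the four categories and sum to 1")
  }
  enr_p <- base_p
  enr_p["target_only"] <- spec$enriched_target_only
  rest <- setdiff(.categories, "target_only")
  enr_p[rest] <- base_p[rest] * (1 - spec$enriched_target_only) /
    (1 - base_p[["target_only"]])
  with_seed(seed, {
    n <- nrow(peaks)
    enriched <- peaks$peak_id %in% enriched_ids
    cat <- character(n)
    if (any(!enriched)) {
      cat[!enriched] <- sample(.categories, sum(!enriched), replace = TRUE,
                               prob = base_p)
    }
    if (any(enriched)) {
      cat[enriched] <- sample(.categories, sum(enriched), replace = TRUE,
                              prob = enr_p)
    }
    carve <- function(which_end) {
      idx <- if (which_end == "left") {
        cat %in% c("both", "target_only")
      } else {
        cat %in% c("both", "other_only")
      }
      p <- peaks[idx, , drop = FALSE]
      w <- pmax(1, pmin(200, floor(p$length / 4)))
      if (which_end == "left") {
        tibble(chrom = p$chrom, start = p$start, end = p$start + w)
      } else {
        tibble(chrom = p$chrom, start = p$end - w, end = p$end)
      }
    }
    target <- carve("left")
    other <- carve("right")
    attr(target, "name") <- "target_hypomethylated"
    attr(other, "name") <- "other_hypomethylated"
    list(target = target, other = other,
         truth = tibble(peak_id = peaks$peak_id, category = cat,
                        enriched = enriched))
  })
}

# one simulated block: ancestral sequence plus branch-specific alterations
gen_block <- function(peak_id, L, spec, rate_human, taxa_rows) {
  base <- c("A", "C", "G", "T")
  anc <- sample(base, L, replace = TRUE)
  kb <- L / 1000
  mutate_base <- function(b) {
    vapply(b, function(x) sample(setdiff(base, x), 1), character(1))
  }
  rows <- matrix(anc, nrow = length(taxa_rows), ncol = L, byrow = TRUE,
                 dimnames = list(taxa_rows, NULL))
  comp_taxa <- spec$comparison_taxa
  arc_taxa <- intersect(spec$archaic_taxa, taxa_rows)

  # comparison-branch substitutions (each taxon its own draw)
  for (tx in comp_taxa) {
    k <- rpois(1, spec$rate_comparison * kb)
    if (k > 0) {
      pos <- sample.int(L, min(k, L))
      rows[tx, pos] <- mutate_base(rows[tx, pos])
    }
  }

  # human deletions first (they claim columns), then substitutions on the
  # remaining columns, then insertions (new columns)
  events <- list()
  claim <- logical(L)
  draw_dels <- function(rate, len_lo, len_hi) {
    k <- rpois(1, rate * kb)
    for (i in seq_len(k)) {
      w <- sample(len_lo:len_hi, 1)
      if (w >= L) next
      s <- sample.int(L - w, 1)
      cols <- s:(s + w - 1)
      if (any(claim[cols])) next
      claim[cols] <<- TRUE
      events[[length(events) + 1L]] <<- list(kind = "deletion", pos = s,
                                             len = w)
    }
  }
  draw_dels(spec$indel_rate_human / 2, 1, 10)
  draw_dels(spec$long_indel_rate_human / 2, 100, 300)
  n_sub <- rpois(1, rate_human * kb)
  free <- which(!claim)
  sub_pos <- if (n_sub > 0 && length(free)) {
    sort(sample(free, min(n_sub, length(free))))
  } else integer()
  for (s in sub_pos) {
    events[[length(events) + 1L]] <- list(kind = "substitution", pos = s,
                                          len = 1L)
  }
  draw_ins <- function(rate, len_lo, len_hi) {
    k <- rpois(1, rate * kb)
    for (i in seq_len(k)) {
      w <- sample(len_lo:len_hi, 1)
      events[[length(events) + 1L]] <<- list(
        kind = "insertion", pos = sample.int(L, 1), len = w,
        seq = sample(base, w, replace = TRUE))
    }
  }
  draw_ins(spec$indel_rate_human / 2, 1, 10)
  draw_ins(spec$long_indel_rate_human / 2, 100, 300)

  hum <- anc
  for (ev in events) {
    if (ev$kind == "substitution") hum[ev$pos] <- mutate_base(anc[ev$pos])
    if (ev$kind == "deletion") hum[ev$pos:(ev$pos + ev$len - 1)] <- "-"
  }
  rows["human", ] <- hum

  # archaic rows: human state by default; ancestral with prob post_split
  arc_states <- list()
  for (tx in arc_taxa) rows[tx, ] <- hum
  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    st <- setNames(character(length(arc_taxa)), arc_taxa)
    for (tx in arc_taxa) {
      ancestral <- runif(1) < spec$archaic_post_split
      st[tx] <- if (ancestral) "ancestral" else "derived"
      if (ancestral && ev$kind != "insertion") {
        cols <- ev$pos:(ev$pos + ev$len - 1)
        rows[tx, cols] <- anc[cols]
      }
    }
    events[[ei]]$arc <- st
  }

  # splice insertions as new alignment columns (gap everywhere but human
  # and the archaic rows that kept the derived state)
  ins <- Filter(function(e) e$kind == "insertion", events)
  if (length(ins)) {
    ord <- order(vapply(ins, `[[`, numeric(1), "pos"))
    ins <- ins[ord]
    segs <- list()
    prev <- 0L
    for (ev in ins) {
      if (ev$pos > prev) {
        segs[[length(segs) + 1L]] <- rows[, (prev + 1L):ev$pos, drop = FALSE]
      }
      w <- length(ev$seq)
      seg <- matrix("-", nrow(rows), w, dimnames = list(rownames(rows), NULL))
      seg["human", ] <- ev$seq
      for (tx in arc_taxa) if (ev$arc[[tx]] == "derived") seg[tx, ] <- ev$seq
      segs[[length(segs) + 1L]] <- seg
      prev <- ev$pos
    }
    if (prev < L) segs[[length(segs) + 1L]] <- rows[, (prev + 1L):L,
                                                    drop = FALSE]
    rows <- do.call(cbind, segs)
  }

  truth <- tibble(
    peak_id = peak_id,
    kind = vapply(events, `[[`, "", "kind"),
    pos = vapply(events, function(e) as.integer(e$pos), integer(1)),
    len = vapply(events, function(e)
      as.integer(if (e$kind == "insertion") length(e$seq) else e$len),
      integer(1)))
  for (tx in arc_taxa) {
    truth[[paste0("state_", tx)]] <- vapply(events, function(e)
      e$arc[[tx]], character(1))
  }
  list(block = tibble(peak_id = peak_id, taxon = rownames(rows),
                      seq = unname(apply(rows, 1, paste, collapse = ""))),
       truth = truth)
}

#' Generate multi-taxon alignment blocks with planted alterations
#'
#' Simulates a star-with-outgroup history per peak: an ancestral sequence
#' receives independent substitutions on each comparison branch (breaking
#' unanimity, so comparison-branch changes never masquerade as
#' human-specific), plus substitutions and short/long indels on the human
#' branch. Archaic taxa copy the human allele at each planted event with
#' probability `1 - archaic_post_split`, else the ancestral allele.
#'
#' @param peaks Peak tibble; one block per peak.
#' @param spec A [generator_spec()].
#' @param seed RNG seed.
#' @param rate_human Human-branch substitution rate per kb (defaults to
#'   `spec$rate_human`; pass a lower value for control-group blocks).
#' @param block_length Ancestral sequence length (`spec$block_length`, or
#'   `NA` to use each peak's own length).
#' @param include_archaic Include archaic rows (default TRUE).
#' @return List with `blocks` (long alignment tibble) and `truth`
#'   (one row per planted event with archaic states).
#' @export
gen_alignment_blocks <- function(peaks, spec, seed = spec$rng_seed,
                                 rate_human = spec$rate_human,
                                 block_length = spec$block_length,
                                 include_archaic = TRUE) {
  taxa_rows <- c("human", spec$comparison_taxa,
                 if (include_archaic) spec$archaic_taxa)
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(peaks)), function(i) {
      L <- if (is.na(block_length)) peaks$length[i] else block_length
      gen_block(peaks$peak_id[i], L, spec, rate_human, taxa_rows)
    })
    list(blocks = validate_alignment_blocks(
           bind_rows(purrr::map(out, "block"))),
         truth = bind_rows(purrr::map(out, "truth")))
  })
}
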