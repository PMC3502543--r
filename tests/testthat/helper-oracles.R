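# Brute-force oracles, written independently of the package internals:
# plain nested loops, no sorting tricks, no Biostrings.

oracle_pairing <- function(peaks, d) {
  mid <- (peaks$start + peaks$end) / 2
  n <- nrow(peaks)
  cnt <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && peaks$chrom[i] == peaks$chrom[j] &&
          abs(mid[i] - mid[j]) < d) {
        cnt <- cnt + 1L
        break
      }
    }
  }
  cnt
}

oracle_membership <- function(peaks, annot) {
  hit <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(annot))) {
      if (peaks$chrom[i] == annot$chrom[j] &&
          peaks$start[i] < annot$end[j] && annot$start[j] < peaks$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.complement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp_pattern <- function(pattern) {
  paste(rev(.complement[strsplit(pattern, "")[[1]]]), collapse = "")
}

# one strand: 0-based start positions where every pattern letter's base set
# contains the sequence letter (so sequence N matches only pattern N)
oracle_scan_strand <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p)
  hits <- integer()
  for (i in seq_len(max(0, length(s) - k + 1))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      letter <- s[i + j - 1]
      if (!(letter %in% .iupac_sets[[p[j]]]) &&
          !(letter == "N" && p[j] == "N")) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_scan <- function(sequence, pattern) {
  fwd <- oracle_scan_strand(sequence, pattern)
  rev <- oracle_scan_strand(sequence, oracle_revcomp_pattern(pattern))
  out <- rbind(
    data.frame(position = fwd, strand = rep("+", length(fwd))),
    data.frame(position = rev, strand = rep("-", length(rev)))
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

# column-by-column event recount with an explicit run state machine
oracle_hsas_block <- function(block, comparison_taxa) {
  seqs <- lapply(setNames(block$seq, block$taxon), function(s)
    strsplit(s, "")[[1]])
  hum <- seqs[["human"]]
  comp <- seqs[comparison_taxa]
  base <- c("A", "C", "G", "T")
  events <- list()
  state <- "none"  # none / del / ins
  run_len <- 0L
  flush <- function(at) {
    if (state != "none") {
      kind <- if (state == "del") "deletion" else "insertion"
      if (run_len >= 100) kind <- "long_indel"
      events[[length(events) + 1L]] <<- data.frame(
        column = at - run_len - 1L, kind = kind, length = run_len)
    }
    state <<- "none"; run_len <<- 0L
  }
  nc <- length(hum)
  for (i in seq_len(nc)) {
    cb <- vapply(comp, `[`, "", i)
    all_base <- all(cb %in% base)
    all_gap <- all(cb == "-")
    agree <- length(unique(cb)) == 1
    if (hum[i] == "-" && all_base && agree) {
      if (state != "del") flush(i)
      state <- "del"; run_len <- run_len + 1L
    } else if (hum[i] %in% base && all_gap) {
      if (state != "ins") flush(i)
      state <- "ins"; run_len <- run_len + 1L
    } else {
      flush(i)
      if (hum[i] %in% base && all_base && agree && hum[i] != cb[1]) {
        events[[length(events) + 1L]] <- data.frame(
          column = i - 1L, kind = "substitution", length = 1L)
      }
    }
  }
  flush(nc + 1L)
  if (!length(events)) {
    return(data.frame(column = integer(), kind = character(),
                      length = integer()))
  }
  out <- do.call(rbind, events)
  out[order(out$column), , drop = FALSE]
}

# full-sort control-peak selection: recompute every pair fold by loops
oracle_controls <- function(density, samples, k, eps = 0.1) {
  m <- as.matrix(density[, -1])
  rownames(m) <- density$peak_id
  sp <- unique(samples$species[samples$cell_type == "NeuN+"])
  means <- sapply(sp, function(s) {
    ids <- samples$sample_id[samples$species == s &
                               samples$cell_type == "NeuN+"]
    rowMeans(m[, intersect(ids, colnames(m)), drop = FALSE])
  })
  score <- numeric(nrow(m))
  for (p in seq_len(nrow(m))) {
    worst <- 0
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      if (i < j) {
        lf <- abs(log2((means[p, i] + eps) / (means[p, j] + eps)))
        if (lf > worst) worst <- lf
      }
    }
    score[p] <- worst
  }
  ids <- rownames(m)
  ids[order(score, ids)][seq_len(k)]
}
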