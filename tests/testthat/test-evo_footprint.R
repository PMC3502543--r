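comp4 <- c("chimpanzee", "gorilla", "orangutan", "macaque")

test_that("substitution, deletion and insertion events are called by unanimity", {
  b <- make_block("ACGTT", "ACGAT")
  h <- count_hsas(b, comp4)
  expect_equal(nrow(h), 1)
  expect_equal(h$kind, "substitution")
  expect_equal(h$column, 3L)
  expect_equal(h$human_allele, "T")
  expect_equal(h$outgroup_allele, "A")

  expect_equal(nrow(count_hsas(make_block("ACGTT", "ACGTT"), comp4)), 0)

  hd <- count_hsas(make_block("AC--T", "ACGGT"), comp4)
  expect_equal(hd$kind, "deletion")
  expect_equal(hd$length, 2L)
  expect_equal(hd$column, 2L)
  expect_equal(hd$outgroup_allele, "GG")

  hi <- count_hsas(make_block("ACGGT", "AC--T"), comp4)
  expect_equal(hi$kind, "insertion")
  expect_equal(hi$length, 2L)
  expect_equal(hi$human_allele, "GG")

  # disagreement among comparison taxa is uninformative, not an HSA
  b2 <- make_block("ACGTT", c("ACGAT", "ACGCT", "ACGAT", "ACGAT"))
  expect_equal(nrow(count_hsas(b2, comp4)), 0)
  # N columns are skipped
  b3 <- make_block("ACGTT", "ACGNT")
  expect_equal(nrow(count_hsas(b3, comp4)), 0)
  expect_error(count_hsas(make_block("ACGTT", "ACGAT"), c(comp4, "gibbon")),
               "gibbon")
})

test_that("runs of 100+ indel columns become one long_indel event", {
  del <- strrep("-", 120)
  keep <- strrep("A", 20)
  b <- make_block(paste0(keep, del, keep),
                  paste0(keep, strrep("G", 120), keep))
  h <- count_hsas(b, comp4)
  expect_equal(h$kind, "long_indel")
  expect_equal(h$length, 120L)
})

test_that("archaic states partition into derived/ancestral/missing", {
  # human T, outgroup A; Neanderthal carries the outgroup allele (post-split
  # alteration), Denisova the human allele
  b <- make_block("ACGTT", "ACGAT",
                  extra = list(neanderthal = "ACGAT", denisova = "ACGTT"))
  h <- count_hsas(b, comp4, archaic_taxa = c("neanderthal", "denisova"))
  expect_equal(h$state_neanderthal, "ancestral")
  expect_equal(h$state_denisova, "derived")
  expect_equal(archaic_fraction(h, "neanderthal"), 1.0)
  expect_equal(archaic_fraction(h, "denisova"), 0.0)

  # a third allele in the archaic is neither
  b2 <- make_block("ACGTT", "ACGAT", extra = list(neanderthal = "ACGCT"))
  h2 <- count_hsas(b2, comp4, archaic_taxa = "neanderthal")
  expect_equal(h2$state_neanderthal, "missing")
  expect_error(archaic_fraction(h2, "neanderthal"), "missing")
  expect_error(archaic_fraction(h2, "unknown_taxon"), "no archaic")
})

test_that("HSA calling is invariant to comparison order and archaic rows", {
  spec <- generator_spec(n_peaks = 6)
  pk <- gen_peak_pool(spec, seed = 101)$peaks
  aln <- gen_alignment_blocks(pk, spec, seed = 102)
  h1 <- count_hsas(aln$blocks, comp4)
  h2 <- count_hsas(aln$blocks, rev(comp4))
  expect_equal(h1, h2)
  no_arc <- aln$blocks[!aln$blocks$taxon %in% c("neanderthal", "denisova"), ]
  h3 <- count_hsas(no_arc, comp4)
  expect_equal(h1, h3)
  # annotated version has identical events, plus the state columns
  h4 <- count_hsas(aln$blocks, comp4, c("neanderthal", "denisova"))
  expect_equal(h4[names(h1)], h1)
})

test_that("random blocks match the column-walking oracle and truth recovery", {
  spec <- generator_spec(rate_human = 15, rate_comparison = 8,
                         indel_rate_human = 2, long_indel_rate_human = 0.1)
  pk <- gen_peak_pool(generator_spec(n_peaks = 20), seed = 111)$peaks
  aln <- gen_alignment_blocks(pk, spec, seed = 112, include_archaic = FALSE)
  h <- count_hsas(aln$blocks, comp4)
  for (id in unique(aln$blocks$peak_id)) {
    got <- h[h$peak_id == id, c("column", "kind", "length")]
    exp <- oracle_hsas_block(aln$blocks[aln$blocks$peak_id == id, ], comp4)
    expect_equal(as.data.frame(got), exp, ignore_attr = TRUE)
  }
  # kinds partition the total
  expect_equal(sum(table(h$kind)), nrow(h))
})

test_that("per-peak rates normalize by ungapped human length", {
  # 3 events in 1500 ungapped human bp -> 2 per kb
  keep <- strrep("A", 1497)
  hum <- paste0("CCC", keep)
  oth <- paste0("GGG", keep)
  b <- make_block(hum, oth, peak_id = "pkA")
  h <- count_hsas(b, comp4)
  expect_equal(nrow(h), 3)
  r <- hsa_rates(h, b)
  expect_equal(r$rate, 2.0)
  expect_equal(r$human_bp, 1500)

  # zero events -> rate 0
  b0 <- make_block("ACGTT", "ACGTT", peak_id = "pkB")
  r0 <- hsa_rates(count_hsas(b0, comp4), b0)
  expect_equal(r0$rate, 0)
  expect_error(hsa_rates(h, make_block("-----", "AAAAA")), "zero-length")
})

test_that("group comparison reproduces exact Wilcoxon p and permutation bounds", {
  g <- compare_groups(c(1, 2, 3), c(4, 5, 6), n_sims = 999, seed = 5)
  expect_equal(g$wilcox_p, 0.1)  # 2 / C(6,3)
  expect_lte(g$perm_p, 0.2)

  same <- compare_groups(c(2, 4, 6, 8), c(2, 4, 6, 8), n_sims = 499,
                         seed = 5)
  expect_equal(same$wilcox_p, 1)
  expect_gt(same$perm_p, 0.5)

  gl <- glance(g)
  expect_equal(gl$wilcox_p, 0.1)
  td <- tidy(g)
  expect_equal(td$mean, c(2, 5))
  expect_error(compare_groups(numeric(), 1:3), "non-empty")
})

test_that("motif tally test reports both chi-square variants coherently", {
  r <- motif_tally_test(10, 355, 4, 375)
  expect_equal(r$prop_a, 10 / 355)
  expect_true(r$pearson_p < r$yates_p)  # continuity correction is conservative
  expect_true(all(c(r$pearson_p, r$yates_p, r$fisher_p) > 0 &
                    c(r$pearson_p, r$yates_p, r$fisher_p) <= 1))
  strong <- motif_tally_test(50, 100, 2, 100)
  expect_lt(strong$pearson_p, 1e-10)
})

test_that("motif scanning handles IUPAC codes, strands and N correctly", {
  m <- scan_motif("CCTGATTAGCC", "WGATTAG")
  expect_equal(m$position, 2L)
  expect_equal(m$strand, "+")
  expect_equal(nrow(scan_motif("AAAA", "WGATTAG")), 0)
  m3 <- scan_motif("ACGT", "NNN")
  expect_equal(m3$position, c(0L, 0L, 1L, 1L))
  expect_setequal(m3$strand, c("+", "-"))
  # sequence N never satisfies a non-N pattern letter
  expect_equal(nrow(scan_motif("CCTGANTAGCC", "WGATTAG")), 0)
  expect_error(scan_motif("ACGT", "WGAU"), "IUPAC")

  withr::with_seed(121, {
    for (i in 1:25) {
      seqc <- paste(sample(c("A", "C", "G", "T", "N"), sample(50:500, 1),
                           replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                    collapse = "")
      pat <- paste(sample(names(.iupac_sets), sample(3:8, 1),
                          replace = TRUE), collapse = "")
      got <- as.data.frame(scan_motif(seqc, pat))
      exp <- oracle_scan(seqc, pat)
      expect_equal(got, exp, ignore_attr = TRUE)
    }
  })
})

test_that("motif gain/loss events resolve orthology through alignment columns", {
  pad <- strrep("C", 10)
  hum <- paste0(pad, "TGATTAG", pad)
  anc <- paste0(pad, "TGATCAG", pad)
  b <- make_block(hum, anc)
  ev <- motif_events(b, "WGATTAG", comp4)
  expect_equal(ev$kind, "gained")
  expect_equal(ev$column, 10L)

  expect_equal(nrow(motif_events(make_block(hum, hum), "WGATTAG", comp4)), 0)

  ev2 <- motif_events(make_block(anc, hum), "WGATTAG", comp4)
  expect_equal(ev2$kind, "lost")

  # a human gap inside the motif still maps the window correctly
  hum_gap <- paste0(pad, "TGA-TAG", pad)
  ev3 <- motif_events(make_block(hum_gap, hum), "WGATTAG", comp4)
  expect_equal(ev3$kind, "lost")
})
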