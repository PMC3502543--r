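test_that("generators are deterministic under a fixed seed", {
  spec <- generator_spec(n_peaks = 120, n_gain = 10, n_clustered = 10)
  a <- gen_peak_pool(spec, seed = 5)
  b <- gen_peak_pool(spec, seed = 5)
  expect_identical(a, b)
  s <- gen_samples(spec)
  ca <- gen_counts(a$peaks, spec, s, seed = 6)
  cb <- gen_counts(a$peaks, spec, s, seed = 6)
  expect_identical(ca, cb)
  aa <- gen_alignment_blocks(head(a$peaks, 4), spec, seed = 7)
  ab <- gen_alignment_blocks(head(a$peaks, 4), spec, seed = 7)
  expect_identical(aa, ab)
  expect_false(identical(gen_peak_pool(spec, seed = 8)$peaks, a$peaks))
})

test_that("peak pools respect bounds, disjointness and planted clustering", {
  spec <- generator_spec(n_peaks = 500, n_clustered = 40,
                         cluster_pair_distance = 4e5)
  out <- gen_peak_pool(spec, seed = 9)
  pk <- out$peaks
  expect_equal(nrow(pk), 500)
  expect_true(all(pk$length >= 500 & pk$length <= 5000))
  # disjoint within chromosome
  by_chr <- split(pk, pk$chrom)
  for (g in by_chr) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # planted pairs sit within the configured midpoint distance
  mids <- (pk$start + pk$end) / 2
  tr <- out$truth
  for (pid in unique(na.omit(tr$pair_id))) {
    idx <- which(tr$pair_id == pid)
    expect_equal(pk$chrom[idx[1]], pk$chrom[idx[2]])
    expect_lt(abs(mids[idx[1]] - mids[idx[2]]), 4e5)
  }
  # empty pool
  expect_equal(nrow(gen_peak_pool(generator_spec(n_peaks = 0))$peaks), 0)
  # infeasible packing is an error
  tiny <- generator_spec(layout = genome_layout("chr1", 1e4),
                         n_peaks = 100)
  expect_error(gen_peak_pool(tiny, seed = 1), "packing")
})

test_that("planted count effects land at the configured fold", {
  spec <- generator_spec(n_peaks = 1500, n_gain = 500, gain_fold = 4,
                         n_human_neun_neg = 0)
  pool <- gen_peak_pool(spec, seed = 11)
  s <- gen_samples(spec)
  out <- gen_counts(pool$peaks, spec, s, seed = 12)
  d <- normalize_density(out$counts, s, pool$peaks)
  m <- as.matrix(d[, -1])
  hum <- rowMeans(m[, s$sample_id[s$species == "human"]])
  oth <- rowMeans(m[, s$sample_id[s$species != "human"]])
  ratio <- mean(hum[out$truth$planted]) / mean(oth[out$truth$planted])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
  ratio0 <- mean(hum[!out$truth$planted]) / mean(oth[!out$truth$planted])
  expect_equal(ratio0, 1, tolerance = 0.1)
})

test_that("dispersion controls overdispersion down to the Poisson limit", {
  # one peak, many identical samples: the count column is 1e4 iid draws
  mk <- function(dispersion) {
    spec0 <- generator_spec(n_peaks = 1, n_gain = 0, dispersion = dispersion,
                            peak_length_range = c(1000, 1000),
                            n_human = 10000, n_chimp = 0, n_macaque = 0,
                            n_human_neun_neg = 0,
                            library_size_range = c(1e7, 1e7))
    pk <- gen_peak_pool(spec0, seed = 13)$peaks
    s <- gen_samples(spec0)
    cnt <- gen_counts(pk, spec0, s, seed = 14)$counts
    as.numeric(cnt[1, -1])
  }
  pois <- mk(0)
  expect_equal(var(pois) / mean(pois), 1, tolerance = 0.1)
  over <- mk(0.2)
  expect_gt(var(over) / mean(over), 2)
})

test_that("annotation categories realize their probabilities and exact truth", {
  spec <- generator_spec(n_peaks = 5000, n_gain = 0)
  pool <- gen_peak_pool(spec, seed = 15)
  ann <- gen_annotations(pool$peaks, spec, seed = 16)
  frac <- prop.table(table(ann$truth$category))
  expect_lt(abs(frac[["both"]] - 0.73), 0.02)
  expect_lt(abs(frac[["target_only"]] - 0.057), 0.02)
  expect_lt(abs(frac[["other_only"]] - 0.005), 0.02)
  expect_lt(abs(frac[["neither"]] - 0.208), 0.02)
  # realized overlap category equals the truth label for every peak
  cc <- categorize_peaks(pool$peaks, ann$target, ann$other)
  expect_identical(cc$category, ann$truth$category)
})

test_that("enriched annotation subsets hit the planted target-only fraction", {
  spec <- generator_spec(n_peaks = 4000, n_gain = 0,
                         enriched_target_only = 0.22)
  pool <- gen_peak_pool(spec, seed = 17)
  planted <- head(pool$peaks$peak_id, 800)
  ann <- gen_annotations(pool$peaks, spec, enriched_ids = planted, seed = 18)
  tr <- ann$truth
  f_in <- mean(tr$category[tr$enriched] == "target_only")
  f_out <- mean(tr$category[!tr$enriched] == "target_only")
  expect_lt(abs(f_in - 0.22), 0.05)
  expect_lt(abs(f_out - 0.057), 0.02)
})

test_that("alignment generation honours zero rates and planted archaic states", {
  quiet <- generator_spec(rate_human = 0, rate_comparison = 0,
                          indel_rate_human = 0, long_indel_rate_human = 0)
  pk <- gen_peak_pool(generator_spec(n_peaks = 5), seed = 19)$peaks
  aln <- gen_alignment_blocks(pk, quiet, seed = 20)
  expect_equal(nrow(aln$truth), 0)
  same <- aln$blocks |>
    dplyr::group_by(peak_id) |>
    dplyr::summarise(k = dplyr::n_distinct(seq))
  expect_true(all(same$k == 1))
  h <- count_hsas(aln$blocks, c("chimpanzee", "gorilla", "orangutan",
                                "macaque"))
  expect_equal(nrow(h), 0)
})
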