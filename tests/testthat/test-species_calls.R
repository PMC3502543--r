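# 3 target vs 2 comparison samples, perfectly separated: the exact
# rank-sum two-sided p is 2 / C(5,2) = 0.2.
toy_call_fixture <- function(h = c(5, 6, 7), c2 = c(1, 2)) {
  list(
    density = make_density(list(H1 = h[1], H2 = h[2], H3 = h[3],
                                C1 = c2[1], C2 = c2[2])),
    samples = make_samples(c("H1", "H2", "H3", "C1", "C2"),
                           c(rep("human", 3), rep("chimpanzee", 2))),
    peaks = make_peaks(0, lengths = 1000)
  )
}

test_that("gain calls use the exact rank-sum p and the fold/length filters", {
  fx <- toy_call_fixture()
  g <- call_gain(fx$density, fx$samples, fx$peaks, "human", "chimpanzee")
  expect_equal(g$p, 0.2)
  expect_equal(g$q, 0.2)
  expect_equal(g$fold_chimpanzee, (6 + 0.1) / (1.5 + 0.1))
  expect_equal(g$label, "none")  # q > 0.05: significance filter holds

  # identical densities in all samples: fold 1, label none
  fx2 <- toy_call_fixture(h = c(3, 3, 3), c2 = c(3, 3))
  g2 <- call_gain(fx2$density, fx2$samples, fx2$peaks, "human", "chimpanzee")
  expect_equal(g2$fold, 1)
  expect_equal(g2$label, "none")

  expect_error(
    call_gain(fx$density, make_samples(c("H1", "H2", "H3", "C1", "C2"),
                                       c(rep("human", 4), "chimpanzee")),
              fx$peaks, "human", "chimpanzee"),
    "2 samples")
})

test_that("depletion mirrors gain with roles reversed", {
  fx <- toy_call_fixture(h = c(1, 2, 1.5), c2 = c(5, 6))
  d <- call_depletion(fx$density, fx$samples, fx$peaks, "human", "chimpanzee")
  expect_equal(d$p, 0.2)
  expect_equal(d$fold_chimpanzee, (5.5 + 0.1) / (1.5 + 0.1))
  expect_true(d$fold > 2)

  # all-zero target densities stay finite through the pseudo-count
  fx0 <- toy_call_fixture(h = c(0, 0, 0), c2 = c(5, 6))
  d0 <- call_depletion(fx0$density, fx0$samples, fx0$peaks, "human",
                       "chimpanzee")
  expect_true(is.finite(d0$fold))
  expect_equal(d0$fold_chimpanzee, (5.5 + 0.1) / 0.1)
})

test_that("relabeling target and comparison swaps gain and loss call sets", {
  spec <- generator_spec(n_peaks = 250, n_gain = 25, n_chimp = 5,
                         n_macaque = 0, n_human_neun_neg = 0)
  pool <- gen_peak_pool(spec, seed = 21)
  samples <- gen_samples(spec)
  cnt <- gen_counts(pool$peaks, spec, samples, seed = 22)
  den <- normalize_density(cnt$counts, samples, pool$peaks)
  uni <- pool$peaks$peak_id
  g <- call_gain(den, samples, pool$peaks, "human", "chimpanzee",
                 universe = uni)
  l <- call_depletion(den, samples, pool$peaks, "chimpanzee", "human",
                      universe = uni)
  expect_equal(l$fold_human, g$fold_chimpanzee)
  expect_equal(l$p, g$p)
  expect_equal(l$peak_id[l$label == "loss"], g$peak_id[g$label == "gain"])
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  spec <- generator_spec(n_peaks = 300, n_gain = 30, n_human_neun_neg = 0)
  pool <- gen_peak_pool(spec, seed = 31)
  samples <- gen_samples(spec)
  cnt <- gen_counts(pool$peaks, spec, samples, seed = 32)
  den <- normalize_density(cnt$counts, samples, pool$peaks)
  g <- call_gain(den, samples, pool$peaks, "human",
                 c("chimpanzee", "macaque"))
  expect_true(all(g$q >= g$p - 1e-12))
  o <- order(g$p)
  expect_true(all(diff(g$q[o]) >= -1e-12))
})

test_that("per-species fold mode never labels more peaks than pooled mode", {
  spec <- generator_spec(n_peaks = 400, n_gain = 60, gain_fold = 3,
                         n_human_neun_neg = 0)
  pool <- gen_peak_pool(spec, seed = 41)
  samples <- gen_samples(spec)
  cnt <- gen_counts(pool$peaks, spec, samples, seed = 42)
  den <- normalize_density(cnt$counts, samples, pool$peaks)
  g_each <- call_gain(den, samples, pool$peaks, "human",
                      c("chimpanzee", "macaque"),
                      analysis_config(fold_mode = "each_species"))
  g_pool <- call_gain(den, samples, pool$peaks, "human",
                      c("chimpanzee", "macaque"),
                      analysis_config(fold_mode = "pooled_average"))
  each_set <- g_each$peak_id[g_each$label == "gain"]
  pool_set <- g_pool$peak_id[g_pool$label == "gain"]
  expect_lte(length(each_set), length(pool_set))
})

test_that("call-set intersection is exact set arithmetic", {
  r <- intersect_calls(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(r$n_overlap, 2)
  expect_equal(r$jaccard, 0.5)
  expect_equal(intersect_calls(c("A"), c("B"))$n_overlap, 0)
  r3 <- intersect_calls(letters[1:5], letters[1:5])
  expect_equal(r3$n_overlap, 5)
  expect_equal(r3$jaccard, 1)
})

test_that("control-peak selection ranks by max |log fold| with a sort oracle", {
  # a peak with identical group means scores 0 and ranks first
  d <- make_density(list(H1 = c(5, 9), H2 = c(5, 2), C1 = c(5, 1),
                         C2 = c(5, 8), M1 = c(5, 3), M2 = c(5, 2)))
  s <- make_samples(c("H1", "H2", "C1", "C2", "M1", "M2"),
                    rep(c("human", "chimpanzee", "macaque"), each = 2))
  pk <- make_peaks(c(0, 5000), lengths = 1000)
  sel <- select_control_peaks(d, s, pk, k = 1)
  expect_equal(sel$peak_id, "pk1")
  expect_equal(sel$score, 0)
  expect_equal(nrow(select_control_peaks(d, s, pk, k = 0)), 0)
  expect_error(select_control_peaks(d, s, pk, k = 5), "pool")

  withr::with_seed(51, {
    n <- 200
    d <- make_density(list(H1 = runif(n, 0, 10), H2 = runif(n, 0, 10),
                           C1 = runif(n, 0, 10), C2 = runif(n, 0, 10),
                           M1 = runif(n, 0, 10), M2 = runif(n, 0, 10)))
    pk <- make_peaks(seq(0, by = 2000, length.out = n), lengths = 800)
    d$peak_id <- pk$peak_id
    sel <- select_control_peaks(d, s, pk, k = 25)
    expect_equal(sel$peak_id, oracle_controls(d, s, 25))
  })
})

test_that("length matching restricts the eligible control pool", {
  s <- make_samples(c("H1", "H2", "C1", "C2"),
                    rep(c("human", "chimpanzee"), each = 2))
  pk <- validate_peaks(tibble::tibble(
    peak_id = c("a", "b", "c"), chrom = "chr1",
    start = c(0, 5000, 20000), end = c(600, 8000, 21000)), toy_layout())
  d <- make_density(list(H1 = c(1, 1, 1), H2 = c(1, 1, 1),
                         C1 = c(1, 1, 1), C2 = c(1, 1, 1)),
                    peak_ids = pk$peak_id)
  sel <- select_control_peaks(d, s, pk, k = 2, target_set = "c",
                              length_window = 500)
  # only a (600) and c (1000) lie within 500 bp of the 1000-bp target
  expect_setequal(sel$peak_id, c("a", "c"))
})

test_that("cell-type restriction keeps neuron-enriched calls only", {
  # equal NeuN+/NeuN- means are excluded; planted neuron-restricted gains
  # are recovered
  spec <- generator_spec(n_peaks = 300, n_gain = 40, n_human_neun_neg = 4)
  pool <- gen_peak_pool(spec, seed = 61)
  samples <- gen_samples(spec)
  cnt <- gen_counts(pool$peaks, spec, samples, seed = 62)
  den <- normalize_density(cnt$counts, samples, pool$peaks)
  g <- call_gain(den, samples, pool$peaks, "human",
                 c("chimpanzee", "macaque"))
  called <- g[g$label == "gain", ]
  neu <- filter_celltype_enriched(called, den, samples)
  # planted folds hit NeuN+ only, so most calls survive the restriction
  expect_gte(nrow(neu) / max(1, nrow(called)), 0.9)
  expect_true(all(neu$q_celltype <= 0.05))

  expect_equal(nrow(filter_celltype_enriched(called[0, ], den, samples)), 0)
  expect_error(
    filter_celltype_enriched(called, den, samples,
                             reference_cell_types = "blood"),
    "blood")

  # a flat peak (no cell-type difference) does not pass
  flat_d <- make_density(list(H1 = 5, H2 = 5, H3 = 5, HN1 = 5, HN2 = 5))
  flat_s <- make_samples(c("H1", "H2", "H3", "HN1", "HN2"),
                         rep("human", 5),
                         cell_type = c(rep("NeuN+", 3), rep("NeuN-", 2)))
  fake_call <- tibble::tibble(peak_id = "pk1", label = "gain")
  expect_equal(nrow(filter_celltype_enriched(fake_call, flat_d, flat_s)), 0)
})
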