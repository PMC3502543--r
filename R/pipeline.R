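# End-to-end orchestration of a self-contained synthetic run:
# simulate -> quantify -> species calls (gain, depletion, neuronal
# restriction, control selection) -> co-localization and overlap
# enrichment -> evolutionary footprint. One global seed is expanded into
# fixed per-stage child seeds so any stage can be re-run in isolation.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    generator = list(n_peaks = 1200, n_gain = 80, n_clustered = 60,
                     rate_human = 20.08),
    analysis = list(n_sims = 1000),
    comparison_species = c("chimpanzee", "macaque"),
    overlap_directions = c(both = "less", target_only = "greater",
                           other_only = "less", neither = "less"),
    footprint = list(n_group = 33, n_control = 32, rate_control = 8.36,
                     motif = "WGATTAG"),
    stages = c("calls", "clustering", "overlap", "footprint")
  )
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      merge_config(base[[nm]], extra[[nm]])
    } else {
      extra[[nm]]
    }
  }
  base
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic cohort with planted ground truth, then runs every
#' analysis stage and scores it against the truth tables. All thresholds
#' come from the config; the run is fully deterministic given `seed`.
#'
#' @param config A nested list, or path to a YAML file, overriding the
#'   defaults (`seed`, `generator` = [generator_spec()] arguments,
#'   `analysis` = [analysis_config()] arguments, `comparison_species`,
#'   `overlap_directions`, `footprint`, `stages`).
#' @param outdir Optional output directory; when given, BED/TSV/JSON
#'   results plus a run manifest are written (byte-identical across reruns
#'   with the same config and seed).
#' @param seed Overrides `config$seed`.
#' @return A `chromdiver_run` list: inputs, per-stage results, and a
#'   `report` list of scored summary numbers.
#' @export
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_all <- merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg_all$seed <- as.integer(seed)
  run_seed <- as.integer(cfg_all$seed)
  spec <- do.call(generator_spec, cfg_all$generator)
  acfg <- do.call(analysis_config,
                  c(cfg_all$analysis, list(rng_seed = run_seed)))
  stages <- cfg_all$stages
  report <- list(seed = run_seed)

  # --- simulate -------------------------------------------------------
  pool_out <- gen_peak_pool(spec, seed = stage_seed(run_seed, "peaks"))
  peaks <- pool_out$peaks
  samples <- gen_samples(spec)
  # planted gains are the first n_gain peaks, which include every planted
  # cluster pair, so clustering and overlap enrichment act on the call set
  planted_ids <- head(peaks$peak_id, spec$n_gain)
  counts_out <- gen_counts(peaks, spec, samples,
                           seed = stage_seed(run_seed, "counts"),
                           planted_ids = planted_ids)
  density <- normalize_density(counts_out$counts, samples, peaks)
  annot <- gen_annotations(peaks, spec, enriched_ids = planted_ids,
                           seed = stage_seed(run_seed, "annotations"))
  truth <- list(pool = pool_out$truth, counts = counts_out$truth,
                annotations = annot$truth)

  results <- list(peaks = peaks, samples = samples, density = density)

  # --- species calls --------------------------------------------------
  if ("calls" %in% stages) {
    gain <- call_gain(density, samples, peaks, spec$gain_species,
                      cfg_all$comparison_species, acfg)
    loss <- call_depletion(density, samples, peaks, spec$gain_species,
                           cfg_all$comparison_species, acfg)
    neuhp <- filter_celltype_enriched(
      gain[gain$label == "gain", , drop = FALSE], density, samples, acfg,
      target_species = spec$gain_species)
    controls <- select_control_peaks(
      density, samples, peaks, k = cfg_all$footprint$n_control, cfg = acfg)
    called <- gain$peak_id[gain$label == "gain"]
    is_planted <- called %in% planted_ids
    report$n_gain_called <- length(called)
    report$gain_sensitivity <- if (spec$n_gain > 0)
      sum(is_planted) / spec$n_gain else NA_real_
    report$gain_fdp <- if (length(called))
      sum(!is_planted) / length(called) else 0
    report$n_loss_called <- sum(loss$label == "loss")
    report$n_neuhp <- nrow(neuhp)
    report$n_controls <- nrow(controls)
    results$gain <- gain
    results$loss <- loss
    results$neuhp <- neuhp
    results$controls <- controls
  }

  gain_set <- if ("calls" %in% stages && report$n_gain_called >= 2) {
    peaks[peaks$peak_id %in% results$gain$peak_id[results$gain$label == "gain"], ]
  } else {
    peaks[peaks$peak_id %in% planted_ids, ]
  }

  # --- co-localization ------------------------------------------------
  if ("clustering" %in% stages) {
    clus <- purrr::map(acfg$distance_thresholds, function(d) {
      enrichment_test(gain_set, peaks, "clustering", d = d,
                      n_sims = acfg$n_sims,
                      seed = stage_seed(run_seed, "clustering"))
    })
    names(clus) <- paste0("d_", acfg$distance_thresholds)
    results$clustering <- clus
    first <- clus[[1]]
    report$clustering_observed <- first$observed
    report$clustering_expected <- first$null_mean
    report$clustering_fold <- first$fold_enrichment
    report$clustering_p <- first$p
  }

  # --- overlap categories ---------------------------------------------
  if ("overlap" %in% stages) {
    dirs <- unlist(cfg_all$overlap_directions)[.categories]
    ov <- enrichment_test(gain_set, peaks, "overlap",
                          annot_target = annot$target,
                          annot_other = annot$other,
                          n_sims = acfg$n_sims,
                          seed = stage_seed(run_seed, "overlap"),
                          direction = unname(dirs))
    results$overlap <- ov
    to <- ov[ov$statistic == "target_only", ]
    report$overlap_target_only_observed <- to$observed
    report$overlap_target_only_expected <- to$null_mean
    report$overlap_target_only_fold <- to$fold_enrichment
    report$overlap_target_only_p <- to$p
  }

  # --- evolutionary footprint -----------------------------------------
  if ("footprint" %in% stages) {
    fp <- cfg_all$footprint
    seed_fp <- stage_seed(run_seed, "footprint")
    grp_peaks <- head(gain_set, fp$n_group)
    ctrl_ids <- if (!is.null(results$controls)) results$controls$peak_id else
      tail(peaks$peak_id, fp$n_control)
    ctrl_peaks <- peaks[peaks$peak_id %in% ctrl_ids, ]
    aln_a <- gen_alignment_blocks(grp_peaks, spec, seed = seed_fp)
    aln_b <- gen_alignment_blocks(ctrl_peaks, spec, seed = seed_fp + 1L,
                                  rate_human = fp$rate_control)
    hsas_a <- count_hsas(aln_a$blocks, spec$comparison_taxa,
                         spec$archaic_taxa)
    hsas_b <- count_hsas(aln_b$blocks, spec$comparison_taxa,
                         spec$archaic_taxa)
    rates_a <- hsa_rates(hsas_a, aln_a$blocks)
    rates_b <- hsa_rates(hsas_b, aln_b$blocks)
    cmp <- compare_groups(rates_a, rates_b, n_sims = acfg$n_sims,
                          seed = seed_fp + 2L)
    motifs <- motif_events(aln_a$blocks, fp$motif, spec$comparison_taxa)
    results$hsas <- hsas_a
    results$rates <- list(group = rates_a, control = rates_b)
    results$group_comparison <- cmp
    results$motifs <- motifs
    report$n_hsas_group <- sum(rates_a$n_hsa)
    report$substitution_fraction <-
      if (nrow(hsas_a)) mean(hsas_a$kind == "substitution") else NA_real_
    report$hsa_rate_group <- cmp$mean_a
    report$hsa_rate_control <- cmp$mean_b
    report$hsa_wilcox_p <- cmp$wilcox_p
    report$hsa_perm_p <- cmp$perm_p
    for (tx in spec$archaic_taxa) {
      report[[paste0("archaic_fraction_", tx)]] <-
        archaic_fraction(hsas_a, tx)
    }
    report$motifs_gained <- sum(motifs$kind == "gained")
    report$motifs_lost <- sum(motifs$kind == "lost")
    truth$alignments <- aln_a$truth
  }

  run <- structure(list(config = cfg_all, seed = run_seed, spec = spec,
                        analysis_config = acfg, truth = truth,
                        results = results, report = report),
                   class = "chromdiver_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# serialize a run's outputs; deterministic byte-for-byte given seed+config
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- run$results
  paths <- character()
  put_tsv <- function(x, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(x, p)
    paths[[name]] <<- p
  }
  write_peaks(res$peaks, file.path(outdir, "peaks.bed"))
  paths[["peaks.bed"]] <- file.path(outdir, "peaks.bed")
  put_tsv(res$samples, "samples.tsv")
  put_tsv(res$density, "density.tsv")
  if (!is.null(res$gain)) put_tsv(res$gain, "calls_gain.tsv")
  if (!is.null(res$loss)) put_tsv(res$loss, "calls_loss.tsv")
  if (!is.null(res$neuhp)) put_tsv(res$neuhp, "calls_neuhp.tsv")
  if (!is.null(res$controls)) put_tsv(res$controls, "control_peaks.tsv")
  if (!is.null(res$clustering)) {
    put_tsv(bind_rows(lapply(res$clustering, as_tibble), .id = "threshold"),
            "clustering.tsv")
  }
  if (!is.null(res$overlap)) put_tsv(as_tibble(res$overlap), "overlap.tsv")
  if (!is.null(res$hsas)) put_tsv(res$hsas, "hsas.tsv")
  if (!is.null(res$motifs)) put_tsv(res$motifs, "motif_events.tsv")
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(run$report, report_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  paths[["report.json"]] <- report_path
  manifest <- list(
    tool = paste0("chromdiver ",
                  as.character(utils::packageVersion("chromdiver"))),
    seed = run$seed,
    stage_seeds = lapply(
      setNames(nm = c("peaks", "counts", "annotations", "calls",
                      "clustering", "overlap", "footprint")),
      function(s) stage_seed(run$seed, s)),
    config = run$config,
    outputs = as.list(setNames(unname(tools::md5sum(unlist(paths))),
                               names(paths)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.chromdiver_run <- function(x, ...) {
  cat("chromdiver synthetic run (seed", x$seed, ")\n")
  rep <- x$report
  for (nm in setdiff(names(rep), "seed")) {
    v <- rep[[nm]]
    cat(sprintf("  %-32s %s\n", nm,
                if (is.numeric(v)) format(signif(v, 4)) else v))
  }
  invisible(x)
}
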