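{
  "seed": 1,
  "n_gain_called": 73,
  "gain_sensitivity": 0.9125,
  "gain_fdp": 0,
  "n_loss_called": 0,
  "n_neuhp": 71,
  "n_controls": 32,
  "clustering_observed": 72,
  "clustering_expected": 27.361,
  "clustering_fold": 2.6314827674,
  "clustering_p": 0.000999000999,
  "overlap_target_only_observed": 20,
  "overlap_target_only_expected": 4.378,
  "overlap_target_only_fold": 4.5682960256,
  "overlap_target_only_p": 0.000999000999,
  "n_hsas_group": 618,
  "substitution_fraction": 0.96278317152,
  "hsa_rate_group": 18.7238672935,
  "hsa_rate_control": 8.0237480843,
  "hsa_wilcox_p": 1.3480049257e-11,
  "hsa_perm_p": 0.000999000999,
  "archaic_fraction_neanderthal": 0.28155339806,
  "archaic_fraction_denisova": 0.28640776699,
  "motifs_gained": 2,
  "motifs_lost": 0
}
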