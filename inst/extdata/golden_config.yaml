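# Packaged synthetic run: the reference configuration whose report is
# recorded in golden_report.json (synthetic data; fixed seed).
seed: 1
generator:
  n_peaks: 1200
  n_gain: 80
  n_clustered: 60
  rate_human: 20.08
analysis:
  n_sims: 1000
footprint:
  n_group: 33
  n_control: 32
  rate_control: 8.36
  motif: WGATTAG
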