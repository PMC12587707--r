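# Demo pipeline configuration: a 46-sample EPIC-like cohort with one
# monoallelic and one mosaic spiked epimutation. Every omitted key takes
# the package default and is echoed into the run manifest.
seed: 7
outdir: epimutr_demo
sim:
  n_samples: 46
  n_probes: 2000
  concentration: 150
  spikes:
    - sample: 1
      island: 1
      f: 1.0
      lambda: 0.7
    - sample: 5
      island: 3
      f: 0.35
      lambda: 1.0
scan:
  q_threshold: 0.005
  min_run: 3
burden:
  case_n: 632
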