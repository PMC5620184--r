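# Pure-simulation demo: a small multi-center cohort with planted
# survival-associated genes, run end to end.
seed: 1
simulate:
  n_patients: 40
  n_dc: 36
  n_probes: 300
  n_controls: 30
  n_planted: 6
  dc_signature_n: 40
  n_reference: 5
discover:
  n_perm: 100
evaluate:
  cutoff_policy: youden
gsea:
  min_size: 5
  n_perm: 100
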