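# Demo pipeline configuration: a small synthetic cohort and a reduced
# permutation count so the full pipeline completes in seconds.
seed: 7
analyses:
  - regional
  - connectivity
  - expression
synthetic:
  n_per_group:
    HC: 16
    DLB_DATPOS: 28
    DLB_DATNEG: 10
    AD: 8
    PD: 6
    MSA: 5
dat_threshold: -2
abnormality_cut: 2
coefficient_display_cut: 0.1
n_perm: 99
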