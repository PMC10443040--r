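# Desk-scale demonstration scenario: a cytidine editor with all three
# guides multiplexed, wild-type controls for background subtraction, and a
# no-guide editor control for the diversity comparison.
gene_fasta: can1_synthetic.fasta
features_tsv: can1_features.tsv
editor:
  type: cytidine
  prob: 0.02
  synergy_factor: 2
depth: 4000
seq_error_rate: 0.001
background_rate: 1.0e-4
parameters:
  min_depth: 2000      # scaled to the scenario depth
  n_trim: 5
  max_mismatch: 0
  min_occurrences: 5
  coverage: 0.95
  max_depth: 600000
samples:
  - sample: AID_g123
    role: edited
    replicates: 3
  - sample: AID
    role: control
    replicates: 3
  - sample: WT
    role: wt
    replicates: 3
pheno:
  strains:
    - name: WT
      true_freq: 1.0e-6
    - name: AID_g123
      true_freq: 1.0e-3
sanger:
  n_clones: 20
  guide: gRNA2
seed: 1
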