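# Small self-contained run: simulate a 40-subject cohort at 30x and
# push it through every stage. Intended as a quick smoke/demo config.
seed: 1
sim:
  n_subjects: 40
  n_cpgs: 600
  n_chroms: 1
  chrom_length: 400000
  island_count: 10
  island_width: 1000
  coverage_mean: 30
  spike_in: true
  planted_linear:
    - {locus: 5, slope: 0.6}
    - {locus: 12, slope: -0.6}
    - {locus: 330, slope: 0.5}
  planted_wave:
    - {locus: 480, center_age: 52, half_width: 5, delta: 25}
    - {locus: 490, center_age: 52, half_width: 5, delta: -25}
  planted_dmr:
    - {island: 3, delta: 25, old_threshold_age: 53}
coverage:
  regression: 10
  swan: 10
  dmr: 2
alpha: 0.05
old_threshold_age: 53
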