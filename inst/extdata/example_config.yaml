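# Example end-to-end configuration: simulate an ascertained case-control
# cohort under the liability-threshold model, then run the full pipeline.
# All values are illustrative synthetic settings.
prevalences_per_100k: [1.25, 63, 495]
drop_variant: mucin_promoter_like
bootstrap:
  n_boot: 10000
  seed: 1
  resample_freq: false
simulate:
  K_per_100k: 63
  n_cases: 792
  n_controls: 10000
  model: liability
  seed: 1
  variants:
    - variant_id: mucin_promoter_like
      p: 0.11
      or_allele: 4.99
    - variant_id: common_low_or_like
      p: 0.806
      or_allele: 1.48
    - variant_id: weak_like
      p: 0.30
      or_allele: 1.25
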