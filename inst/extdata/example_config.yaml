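# Example study configuration for a three-model epilepsy severity run.
# Groups map to the binary burden classifier: 1 = with burden
# (treated/epileptic), 0 = without burden (sham-implanted controls);
# naive non-implanted animals are excluded from ROC screening.
group_burden_map:
  naive: exclude
  sham: 0
  treated: 1
groups: [naive, sham, treated]
exclusion_list:
  body_weight_g: "weight gain reflects altered appetite regulation, not distress"
  body_weight_change_pct: "weight gain reflects altered appetite regulation, not distress"
r_significant: 0.5
r_redundant: 0.7
p_cut: 0.05
missingness_cut: 0.2
train_fraction: 0.8
n_resamples: 100
sd_threshold: 1.0
cluster_k: 6
cluster_resamples: 100
ci_level: 0.95
seed: 7
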