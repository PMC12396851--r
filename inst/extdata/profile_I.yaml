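# Classification profile I: literature-adapted ACMG/AMP rule settings.
# The rarity criterion (PM2) keeps its original moderate strength.
profile_id: I
pm2_strength: moderate
prevalence: 0.01
heterogeneity_ba1: 0.05
heterogeneity_pm2: 0.01
revel_pathogenic: 0.644
spliceai_high: 0.9
revel_benign: 0.29
spliceai_benign: 0.1
bs2_min_controls: 1
penetrance: 1
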