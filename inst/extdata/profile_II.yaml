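# Classification profile II: diagnostics-grade refinement for NOA.
# PM2 is demoted to supporting strength, reflecting current
# recommendations on population allele-rarity evidence; frequency
# thresholds derive from a 1% azoospermia prevalence with 5% (BA1) or
# 1% (PM2/BS1/BS2) combined genetic and allelic heterogeneity.
profile_id: II
pm2_strength: supporting
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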