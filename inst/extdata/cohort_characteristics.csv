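cohort,n,n_female,birth_weight_mean_g,birth_weight_sd_g,pma_birth_mean_wks,pma_birth_sd_wks,scan_pma_means,scan_pma_sds,n_prepandemic
fetal_neonatal,29,13,3646,640,39.4,1.5,31.2;35.3;43.4,0.7;0.8;1.3,14
neonatal,31,19,3510,377,39.9,0.8,44.4,1.3,NA
dhcp,24,9,3438,423,39.4,1.6,40.2,2.1,NA
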