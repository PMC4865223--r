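category,count
snps_available_ds,17543
snps_available_bwr,1356
targeted_ds,4352
targeted_epo,1888
not_captured,939
monomorphic,768
het_only,160
er_clean,2822
bonus_clean,2305
bonus_on_targeted_contig,895
bonus_one_per_contig,968
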