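quantity	case	control
transitions	2066576	1843133
transversions	983003	884403
homozygous_snvs	2927627	2623154
high_quality_snvs	3049694	2727649
truth_variant_positions	7368	4000
truth_called_positions	6984	3319
truth_invariant_positions	2491	1372
truth_confirmed_invariant	2489	1104
group1_snvs	48573	NA
group2_snvs	1258423	NA
group3_snvs	47735	NA
group4_snvs	2	NA
group5_snvs	6	NA
group1_indels	6731	NA
group2_indels	110171	NA
group3_indels	17647	NA
group4_indels	1	NA
group5_indels	4	NA
pav_genes_total	252	NA
pav_genes_olfactory	60	NA
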