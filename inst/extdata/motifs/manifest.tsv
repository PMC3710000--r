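id	class	min_size	file
osc_selfinh	oscillation	3	osc_selfinh.tsv
osc_negfb2	oscillation	3	osc_negfb2.tsv
osc_negfb2_selfact	oscillation	NA	osc_negfb2_selfact.tsv
osc_negfb2_selfinh	oscillation	3	osc_negfb2_selfinh.tsv
osc_negfb2_dualself	oscillation	NA	osc_negfb2_dualself.tsv
adapt_nfblb	adaptation	NA	adapt_nfblb.tsv
adapt_iffl	adaptation	NA	adapt_iffl.tsv
bist_selfact	bistable_switch	NA	bist_selfact.tsv
bist_mutual_act	bistable_switch	NA	bist_mutual_act.tsv
bist_mutual_inh	bistable_switch	NA	bist_mutual_inh.tsv
bist_mutual_act_selfact	bistable_switch	NA	bist_mutual_act_selfact.tsv
bist_mutual_inh_selfact	bistable_switch	NA	bist_mutual_inh_selfact.tsv
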