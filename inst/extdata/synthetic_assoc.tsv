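variant_id	p_ctrl	beta	se_beta	n_ctrl
mucin_promoter_like	0.11	1.607436	0.08	10000
common_low_or_like	0.806	0.392042	0.06	10000
protective_like	0.45	-0.010050	0.07	10000
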