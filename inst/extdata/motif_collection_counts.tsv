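set	category	count
new	composite	1131
new	spacing	205
new	ht_selex	12
prior	mouse_ht_selex	133
prior	human_ht_selex	687
prior	human_ht_selex_2	31
prior	cap_selex	562
prior	e2f8	1
prior	human_misc	10
prior	ht_selex_batch2	864
prior	methyl_selex	297
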