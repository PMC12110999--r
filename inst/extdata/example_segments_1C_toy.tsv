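chromosome	start_cM	end_cM	ibd_state
1	0	100	0
2	0	50	0
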