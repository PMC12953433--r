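reaction_id	v_star
r_AtoB	1.5
r_Auptake	1.5
r_Bexport	1.5
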