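system,label,shift_kcal
cb6,remove_d2_gto,64.51
bcd,remove_d2_gto,27.85
cb6,to_d3_gto,18.8
bcd,to_d3_gto,1.46
cb6,remove_d2_pw,63.17
bcd,remove_d2_pw,26.76
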