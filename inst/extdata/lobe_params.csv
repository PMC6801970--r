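parameter,value
l_pi_n_angstrom,0.574
l_pi_o_angstrom,0.461
pop_n,0.45
pop_o,0.51
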