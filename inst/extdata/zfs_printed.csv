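configuration,r_oo_angstrom,d_cm1
config1,8,3.34e-3
config1,9,2.40e-3
config2,8,3.47e-3
config2,9,2.42e-3
config1,5,-0.1390
config1,5.5,-0.0418
config2,5,-0.1426
config2,5.5,-0.0759
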