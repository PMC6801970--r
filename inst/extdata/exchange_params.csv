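law,j0_cm1,j0_err_cm1,a_inv_angstrom,a_err_inv_angstrom
ferro,7663.86,239.5,2.812,0.01
config2,-193935,13520,3.112,0.023
antiferro0,-193496,11280,3.080,0.023
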