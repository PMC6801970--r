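basis,de_cb6_kcal,de_corr_cb6_kcal,de_bcd_kcal,de_corr_bcd_kcal
6-31G,3.91,24.55,-36.51,-25.09
6-31+G,6.33,23.61,-34.98,-25.75
6-31++G,6.06,23.62,-34.72,-25.73
6-31G*,4.15,24.26,-34.75,-23.71
6-31+G*,13.75,22.76,-29.39,-24.52
6-31++G*,13.65,22.77,-29.45,-24.51
6-31G**,2.64,22.99,-35.12,-24.33
6-31+G**,12.63,21.53,-29.53,-25.17
6-31++G**,12.56,21.53,-29.53,-25.15
6-311G,4.73,23.73,-33.60,-25.00
6-311+G,4.76,24.34,-34.91,-25.24
6-311++G,4.86,24.46,-35.17,-25.23
6-311G*,5.58,22.83,-32.30,-24.19
6-311+G*,13.09,23.19,-30.16,-24.54
6-311++G*,13.21,23.25,-30.29,-24.52
6-311G**,5.14,22.07,-32.68,-24.91
6-311+G**,13.1,22.1,-29.70,-25.23
6-311++G**,13.17,22.13,-29.64,-25.22
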