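e_cut_au,e_a_hartree,e_b_hartree,e_ab_hartree,de_kcal
10,-89.808568,-843.193164,-933.080225,-49.255
15,-91.429465,-864.977950,-956.457872,-31.662
20,-92.003204,-874.457998,-966.508544,-29.707
25,-92.155612,-877.393910,-969.588669,-24.565
30,-92.187830,-878.113239,-970.339341,-24.016
35,-92.193473,-878.238044,-970.469690,-23.954
40,-92.195163,-878.253100,-970.486430,-23.950
Inf,-92.213100,-878.724000,-970.972000,-21.900
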