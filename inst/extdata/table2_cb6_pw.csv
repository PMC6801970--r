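e_cut_au,e_a_hartree,e_b_hartree,e_ab_hartree,de_kcal
10,-89.752721,-666.521144,-756.272743,0.704
15,-91.420119,-682.677029,-774.078638,11.615
20,-91.955313,-688.117167,-780.046476,16.318
25,-92.127097,-689.949014,-782.046661,18.480
30,-92.182236,-690.565848,-782.717044,19.477
Inf,-92.208300,-690.879000,-783.055000,20.269
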