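age_wk,sigma2_a,sigma2_d,sigma2_e,sigma2_p_published,h2_published,se_h2_published,d_ratio_published
0,13.49,0.00,0.00,13.49,1.00,0.00,0.00
2,165.71,0.00,344.25,509.96,0.32,0.10,0.00
4,3721.66,0.00,702.17,4423.83,0.84,0.03,0.00
6,14250.04,3314.70,712.57,18277.31,0.78,0.03,0.18
8,14030.04,1118.85,10033.81,25182.69,0.56,0.03,0.04
10,15629.51,6021.84,14661.96,36313.32,0.43,0.03,0.17
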