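sample,medium,protein_conc_mg_ml,tm_c,tm_sd_c
Lys in water (DSC curve),water,1.0,74.56,0.835
Lys in water (control),water,1.0,73.71,0.004
Lys + [N1112(OH)][C4F9SO3] above 1st CAC (transition 1),aqueous FIL,1.0,80.04,NA
Lys + [N1112(OH)][C4F9SO3] above 1st CAC (transition 2),aqueous FIL,1.0,83.39,NA
Lys + [N1112(OH)][C4F9SO3] above 1st CAC (transition 3),aqueous FIL,1.0,86.40,NA
Lys resuspended from BP#5 FIL-rich phase,water,1.0,69.04,0.005
Lys resuspended from BP#7 FIL-rich phase,water,1.0,68.43,0.004
Lys resuspended from BP#8 FIL-rich phase,water,1.0,69.15,0.013
BSA in water,water,1.0,73.71,0.004
Lys in BP#10 [N1112(OH)][H2PO4]-rich phase,ABS phase,1.0,76.31,0.005
Lys in BP#12 [N1112(OH)][H2PO4]-rich phase,ABS phase,0.5,66.70,0.008
Lys in BP#11 [N1112(OH)][H2PO4]-rich phase,ABS phase,1.0,54.89,0.012
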