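fine,coarse
CD4_T,lymphoid
CD8_T,lymphoid
NK,lymphoid
B_naive,lymphoid
B_memory,lymphoid
Plasma,lymphoid
MAIT,lymphoid
CD14_Mono,myeloid
CD16_Mono,myeloid
cDC,myeloid
pDC,myeloid
Megakaryocyte,myeloid
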