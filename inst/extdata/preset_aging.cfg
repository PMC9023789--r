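# celldiv simulation config
panel: CD4_T, CD8_T, NK, B_naive, B_memory, Plasma, MAIT, CD14_Mono, CD16_Mono, cDC, pDC, Megakaryocyte
cells_per_sample: 300, 1200
seed: 1
group: younger
n_samples: 12
alpha: 9.0, 6.0, 3.0, 2.5, 1.5, 0.3, 0.7, 4.0, 1.0, 0.8, 0.5, 0.7
group: middle
n_samples: 26
alpha: 8.5, 6.5, 3.2, 2.3, 1.4, 0.3, 0.8, 4.2, 1.1, 0.8, 0.4, 0.5
group: older
n_samples: 14
alpha: 8.0, 6.0, 3.5, 2.0, 1.3, 0.4, 0.8, 4.8, 1.4, 0.9, 0.4, 0.5
group: extreme_old
n_samples: 14
alpha: 4.5, 4.0, 3.0, 2.0, 1.5, 0.8, 1.2, 6.0, 2.8, 1.8, 1.0, 1.4
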