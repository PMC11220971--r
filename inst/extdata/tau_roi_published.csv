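roi,estimate,p_raw,p_fdr_published
bankssts,0.042,0.448,0.976
caudal anterior cingulate,-0.067,0.311,0.976
caudal middle frontal,-0.026,0.617,0.976
cuneus,0.089,0.102,0.976
frontal pole,0.089,0.277,0.976
fusiform,0.008,0.870,0.976
inferior parietal,0.023,0.615,0.976
inferior temporal,0.034,0.543,0.976
insula,-0.049,0.309,0.976
isthmus cingulate,-0.045,0.377,0.976
lateral occipital,0.094,0.156,0.976
lateral orbitofrontal,-0.013,0.813,0.976
lingual,0.044,0.330,0.976
medial orbitofrontal,-0.029,0.643,0.976
middle temporal,0.012,0.804,0.976
paracentral,-0.137,0.015,0.490
parahippocampal,0.029,0.608,0.976
pars opercularis,0.043,0.418,0.976
pars orbitalis,0.012,0.849,0.976
pars triangularis,0.036,0.507,0.976
pericalcarine,0.063,0.325,0.976
postcentral,-0.057,0.151,0.976
posterior cingulate,-0.003,0.946,0.976
precentral,0.010,0.786,0.976
precuneus,-0.045,0.384,0.976
rostral anterior cingulate,-0.024,0.694,0.976
rostral middle frontal,-0.001,0.980,0.980
superior frontal,-0.016,0.745,0.976
superior parietal,-0.006,0.907,0.976
superior temporal,0.004,0.934,0.976
supramarginal,0.023,0.595,0.976
temporal pole,0.004,0.943,0.976
transverse temporal,-0.032,0.682,0.976
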