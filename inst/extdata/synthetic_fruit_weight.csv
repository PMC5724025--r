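group,weight
CT,0.12
CT,0.18
CT,0.22
CT,0.31
CT,0.55
CT,1.02
MMT,0.15
MMT,0.16
MMT,0.16
MMT,0.17
MMT,0.17
MMT,0.15
MFT,0.14
MFT,0.17
MFT,0.19
MFT,0.21
MFT,0.24
MFT,0.18
HSP,0.31
HSP,0.42
HSP,0.51
HSP,0.62
HSP,0.75
HSP,0.69
HCP,0.44
HCP,0.51
HCP,0.55
HCP,0.60
HCP,0.68
HCP,0.64
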