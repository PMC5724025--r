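plant_id,treatment,flowers,fruits
CT_01,CT,10,10
CT_02,CT,10,10
CT_03,CT,10,9
CT_04,CT,10,9
CT_05,CT,10,8
CT_06,CT,10,7
CT_07,CT,10,6
CT_08,CT,10,5
CT_09,CT,10,4
CT_10,CT,10,2
MMT_01,MMT,10,10
MMT_02,MMT,10,10
MMT_03,MMT,10,10
MMT_04,MMT,10,10
MMT_05,MMT,10,10
MMT_06,MMT,10,10
MMT_07,MMT,10,10
MMT_08,MMT,10,10
MMT_09,MMT,10,10
MMT_10,MMT,10,10
MFT_01,MFT,10,10
MFT_02,MFT,10,10
MFT_03,MFT,10,10
MFT_04,MFT,10,10
MFT_05,MFT,10,10
MFT_06,MFT,10,10
MFT_07,MFT,10,9
MFT_08,MFT,10,9
MFT_09,MFT,10,8
MFT_10,MFT,10,6
HCP_01,HCP,10,10
HCP_02,HCP,10,10
HCP_03,HCP,10,10
HCP_04,HCP,10,10
HCP_05,HCP,10,6
HCP_06,HCP,10,0
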