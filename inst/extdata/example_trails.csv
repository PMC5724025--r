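treatment,insect_id,taxon,z,n
CT,i01,Apis mellifera,1,9
CT,i02,Apis mellifera,0,5
CT,i03,Plebeia sp.,2,11
CT,i04,Apis mellifera,1,6
MMT,i05,Apis mellifera,0,7
MMT,i06,Apis mellifera,1,4
MMT,i07,Palpada rufipedes,0,5
MFT,i08,Apis mellifera,2,8
MFT,i09,Apis mellifera,1,3
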