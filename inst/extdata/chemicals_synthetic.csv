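sample_id,chemical_id,category,concentration_ng_L
W01,mebendazole,pharmaceutical,38
W01,hexadecyltrimethylammonium,industrial,5200
W01,1H-benzotriazole,industrial,860
W01,estrone,pharmaceutical,0.9
W01,bisphenol_A,polymer_additive,310
W01,fluoranthene,industrial,12
W01,metolachlor,pesticide,45
W02,mebendazole,pharmaceutical,11
W02,1H-benzotriazole,industrial,1500
W02,estrone,pharmaceutical,0.4
W02,bisphenol_A,polymer_additive,95
W02,fluoranthene,industrial,31
W02,metolachlor,pesticide,120
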