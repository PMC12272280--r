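chemical_id,assay_id,ec10,unit
narciclasine,SHSY5Y,1000,ng/L
mebendazole,SHSY5Y,27247.9564032698,ng/L
hexadecyltrimethylammonium,SHSY5Y,52000,ng/L
1H-benzotriazole,SHSY5Y,8300000,ng/L
estradiol,ERalpha,0.68,ng/L
estrone,ERalpha,17,ng/L
bisphenol_A,ERalpha,54000,ng/L
benzo[a]pyrene,AhR,500,ng/L
fluoranthene,AhR,91000,ng/L
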