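species,id,location,n,num,eff_num,ho,hs,ht,gis
Trioxys pallidus,J0178,Yuba City,7,2.333,1.801,0.217,0.393,0.393,0.448
Trioxys pallidus,J0057,Arbuckle,14,3.333,1.822,0.295,0.374,0.374,0.210
Trioxys pallidus,J0073,Upper Lake,13,2.933,1.710,0.264,0.334,0.334,0.211
Trioxys pallidus,J0179,Escalon,12,3.067,1.833,0.265,0.352,0.352,0.245
Trioxys pallidus,J0188,Newark,10,2.867,1.869,0.347,0.389,0.389,0.107
Chromaphis juglandicola,A0052,Linden,7,1.500,1.208,0.119,0.139,0.139,0.143
Chromaphis juglandicola,A0057,Arbuckle,12,2.333,1.615,0.201,0.362,0.362,0.444
Chromaphis juglandicola,A0070,Upper Lake,9,1.667,1.288,0.179,0.197,0.197,0.089
Chromaphis juglandicola,A0046,Escalon,9,1.500,1.152,0.102,0.097,0.097,-0.048
Chromaphis juglandicola,A0189,Newark,12,1.833,1.259,0.160,0.167,0.167,0.043
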