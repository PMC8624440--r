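snv_id,gene,locus,risk_allele,other_allele,risk_allele_freq,location_class
rs3807989,CAV1,7q31,G,A,0.61,intron
rs11047543,SOX5,12p12,A,G,0.10,upstream
rs28631169,MYH7,14q11,T,C,0.12,intron
rs2106261,ZFHX3,16q22,T,C,0.24,intron
rs13376333,KCNN3,1q21,T,C,0.27,intron
rs75190942,KCNJ5,11q24,A,C,0.09,downstream
rs2200733,PITX2,4q25,T,C,0.15,upstream
rs6838973,PITX2,4q25,C,T,0.43,upstream
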