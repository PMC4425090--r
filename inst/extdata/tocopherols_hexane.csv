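analyte,mean,sd,n,unit
acetate,<5,NA,3,mg_per_kg_fat
alpha,292,10,3,mg_per_kg_fat
beta,3.3,0.6,3,mg_per_kg_fat
gamma,488,10,3,mg_per_kg_fat
delta,14.3,0.58,3,mg_per_kg_fat
alpha_tocotrienol,<2,NA,3,mg_per_kg_fat
beta_tocotrienol,<2,NA,3,mg_per_kg_fat
gamma_tocotrienol,<2,NA,3,mg_per_kg_fat
delta_tocotrienol,<2,NA,3,mg_per_kg_fat
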