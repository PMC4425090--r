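analyte,mean,sd,n,unit
acetate,<5,NA,3,mg_per_kg_fat
alpha,277,28,3,mg_per_kg_fat
beta,3.5,0.7,3,mg_per_kg_fat
gamma,443,13,3,mg_per_kg_fat
delta,13.3,0.6,3,mg_per_kg_fat
alpha_tocotrienol,<2,NA,3,mg_per_kg_fat
beta_tocotrienol,<2,NA,3,mg_per_kg_fat
gamma_tocotrienol,<2,NA,3,mg_per_kg_fat
delta_tocotrienol,<2,NA,3,mg_per_kg_fat
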