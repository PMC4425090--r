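name,delta_d,delta_p,delta_h,cp,t_boil,dh_vap,density,t_melt,viscosity,price
n-hexane,14,0,0,2.27,69,328,0.675,-95,0.31,0.9
MeTHF,16.4,4.7,4.6,1.758,80,375,0.855,-136,0.60,5
d-limonene,16.7,1.8,3.1,NA,176,NA,0.841,-74,NA,NA
p-cymene,17.3,2.3,2.4,NA,177,NA,0.857,-68,NA,NA
methylacetate,15.5,7.2,7.6,NA,57,NA,0.932,-98,NA,NA
ethylacetate,15.8,5.3,7.2,NA,77,NA,0.902,-84,NA,NA
butanol,16,5.7,15.8,NA,118,NA,0.810,-90,NA,NA
IPA,15.8,6.1,16.4,NA,83,NA,0.786,-89,NA,NA
ethanol,15.8,8.8,19.4,NA,78,NA,0.789,-114,NA,NA
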