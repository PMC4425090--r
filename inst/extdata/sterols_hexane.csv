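analyte,mean,sd,n,unit
cholesterol,0.33,0.06,3,pct_identified_sterols
brassicasterol,8.03,0.06,3,pct_identified_sterols
24-methyl-cholesterol,1.23,0.12,3,pct_identified_sterols
campesterol,37.47,0.06,3,pct_identified_sterols
campestanol,0.10,0.00,3,pct_identified_sterols
stigmasterol,0.20,0.00,3,pct_identified_sterols
d7-campesterol,0.27,0.06,3,pct_identified_sterols
d5.23-stigmastadienol,0.23,0.06,3,pct_identified_sterols
clerosterol,0.60,0.00,3,pct_identified_sterols
beta-sitosterol,48.30,0.30,3,pct_identified_sterols
sitostanol,0.20,0.00,3,pct_identified_sterols
d5-avenasterol,2.20,0.10,3,pct_identified_sterols
d5.24-stigmastadienol,0.50,0.00,3,pct_identified_sterols
d7-stigmasterol,0.10,0.00,3,pct_identified_sterols
d7-avenasterol,0.25,0.21,3,pct_identified_sterols
total_mg_per_100g,881,14,3,mg_per_100g
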