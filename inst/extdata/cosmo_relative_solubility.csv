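solvent,TAG1,TAG2,TAG3,TAG4,T1,T2,S1,S2,S3
n-hexane,-0.3797,0,0,0,-0.159,-0.1363,-0.4468,-0.4773,-0.4940
MeTHF,0,0,0,0,0,0,0,0,0
d-limonene,0,0,0,0,0,-0.0229,-0.4030,-0.4162,-0.4023
p-cymene,0,0,0,0,-0.0040,-0.0787,-0.4805,-0.4842,-0.4556
methylacetate,0,-0.0463,-0.5269,-0.2164,0,0,-0.2423,-0.2101,-0.1229
ethylacetate,0,0,0,0,0,0,0,0,0
butanol,-0.7385,-1.0072,-0.9738,-1.1775,-0.4340,-0.3684,-0.1987,-0.1645,-0.1540
IPA,-0.7811,-1.1702,-1.1342,-1.3628,-0.4607,-0.7938,-0.2375,-0.1996,-0.1789
ethanol,-1.4208,-2.0056,-1.9840,-2.2436,-0.8844,-0.1363,-0.5411,-0.4857,-0.4508
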