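label,lobe,middle_mean,elderly_mean,p_value
CACg(L),frontal,2.1081,2.0668,0.037
Tr(L),frontal,2.2499,2.2334,0.044
RoMF(L),frontal,2.4128,2.3997,0.005
RoMF(R),frontal,2.4128,2.4014,0.048
MT(L),temporal,2.3118,2.2989,0.043
MT(R),temporal,2.3254,2.3103,0.018
ST(L),temporal,2.3267,2.3148,0.033
ST(R),temporal,2.3392,2.329,0.037
PaH(L),temporal,2.0762,2.0536,0.035
IT(R),temporal,2.3278,2.3138,0.031
PoCg(L),parietal,2.1961,2.1684,0.038
PreCu(L),parietal,2.3302,2.3171,0.045
SP(L),parietal,2.3567,2.3487,0.031
SP(R),parietal,2.3567,2.3487,0.016
PerCa(L),occipital,2.0416,2.0935,0.0009
PerCa(R),occipital,2.0836,2.1097,0.04
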