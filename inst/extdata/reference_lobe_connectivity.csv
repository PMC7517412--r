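scope,lobe,column,middle,elderly,ratio_printed
intra,frontal,total,0.3986,0.3686,92.4
intra,frontal,left,0.4552,0.4168,91.6
intra,frontal,right,0.3421,0.3211,93.8
intra,temporal,total,0.3351,0.4239,126.5
intra,temporal,left,0.3127,0.3867,123.7
intra,temporal,right,0.3575,0.4488,125.6
intra,parietal,total,0.3779,0.3378,89.4
intra,parietal,left,0.426,0.3576,83.9
intra,parietal,right,0.3298,0.3195,96.9
intra,occipital,total,0.3876,0.4642,119.8
intra,occipital,left,0.3551,0.4309,121.3
intra,occipital,right,0.4207,0.5012,119.1
inter,frontal,total,0.7119,0.6345,89.1
inter,frontal,left,0.7131,0.636,89.2
inter,frontal,right,0.7106,0.633,89.1
inter,temporal,total,0.7088,0.6546,92.3
inter,temporal,left,0.7087,0.658,92.8
inter,temporal,right,0.7089,0.6512,91.9
inter,parietal,total,0.7104,0.6265,88.1
inter,parietal,left,0.7099,0.6405,90.2
inter,parietal,right,0.7108,0.6125,86.1
inter,occipital,total,0.7134,0.6341,88.8
inter,occipital,left,0.7137,0.6383,89.4
inter,occipital,right,0.7131,0.63,88.4
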