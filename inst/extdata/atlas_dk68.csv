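index,name,abbreviation,hemisphere,lobe
1,caudal anterior cingulate,CACg,left,frontal
2,caudal anterior cingulate,CACg,right,frontal
3,caudal middle frontal,CMF,left,frontal
4,caudal middle frontal,CMF,right,frontal
5,lateral orbitofrontal,LOrF,left,frontal
6,lateral orbitofrontal,LOrF,right,frontal
7,medial orbitofrontal,MOrF,left,frontal
8,medial orbitofrontal,MOrF,right,frontal
9,paracentral,PaC,left,frontal
10,paracentral,PaC,right,frontal
11,pars opercularis,Op,left,frontal
12,pars opercularis,Op,right,frontal
13,pars orbitalis,Or,left,frontal
14,pars orbitalis,Or,right,frontal
15,pars triangularis,Tr,left,frontal
16,pars triangularis,Tr,right,frontal
17,precentral,PreC,left,frontal
18,precentral,PreC,right,frontal
19,rostral anterior cingulate,RoACg,left,frontal
20,rostral anterior cingulate,RoACg,right,frontal
21,rostral middle frontal,RoMF,left,frontal
22,rostral middle frontal,RoMF,right,frontal
23,superior frontal,SF,left,frontal
24,superior frontal,SF,right,frontal
25,frontal pole,FPol,left,frontal
26,frontal pole,FPol,right,frontal
27,insula,Ins,left,frontal
28,insula,Ins,right,frontal
29,banks of superior temporal sulcus,B,left,temporal
30,banks of superior temporal sulcus,B,right,temporal
31,entorhinal,En,left,temporal
32,entorhinal,En,right,temporal
33,fusiform,Fu,left,temporal
34,fusiform,Fu,right,temporal
35,inferior temporal,IT,left,temporal
36,inferior temporal,IT,right,temporal
37,middle temporal,MT,left,temporal
38,middle temporal,MT,right,temporal
39,parahippocampal,PaH,left,temporal
40,parahippocampal,PaH,right,temporal
41,superior temporal,ST,left,temporal
42,superior temporal,ST,right,temporal
43,temporal pole,TPol,left,temporal
44,temporal pole,TPol,right,temporal
45,transverse temporal,TrT,left,temporal
46,transverse temporal,TrT,right,temporal
47,inferior parietal,IP,left,parietal
48,inferior parietal,IP,right,parietal
49,isthmus cingulate,IstCg,left,parietal
50,isthmus cingulate,IstCg,right,parietal
51,postcentral,PoC,left,parietal
52,postcentral,PoC,right,parietal
53,posterior cingulate,PoCg,left,parietal
54,posterior cingulate,PoCg,right,parietal
55,precuneus,PreCu,left,parietal
56,precuneus,PreCu,right,parietal
57,superior parietal,SP,left,parietal
58,superior parietal,SP,right,parietal
59,supramarginal,SM,left,parietal
60,supramarginal,SM,right,parietal
61,cuneus,Cu,left,occipital
62,cuneus,Cu,right,occipital
63,lateral occipital,LO,left,occipital
64,lateral occipital,LO,right,occipital
65,lingual,Lg,left,occipital
66,lingual,Lg,right,occipital
67,pericalcarine,PerCa,left,occipital
68,pericalcarine,PerCa,right,occipital
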