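"code","name","abbreviation","hemisphere"
1,"Precentral gyrus left","PreCG.L","L"
2,"Precentral gyrus right","PreCG.R","R"
3,"Superior frontal gyrus dorsolateral left","SFGdor.L","L"
4,"Superior frontal gyrus dorsolateral right","SFGdor.R","R"
5,"Superior frontal gyrus orbital part left","ORBsup.L","L"
6,"Superior frontal gyrus orbital part right","ORBsup.R","R"
7,"Middle frontal gyrus left","MFG.L","L"
8,"Middle frontal gyrus right","MFG.R","R"
9,"Middle frontal gyrus orbital part left","ORBmid.L","L"
10,"Middle frontal gyrus orbital part right","ORBmid.R","R"
11,"Inferior frontal gyrus opercular part left","IFGoperc.L","L"
12,"Inferior frontal gyrus opercular part right","IFGoperc.R","R"
13,"Inferior frontal gyrus triangular part left","IFGtriang.L","L"
14,"Inferior frontal gyrus triangular part right","IFGtriang.R","R"
15,"Inferior frontal gyrus orbital part left","ORBinf.L","L"
16,"Inferior frontal gyrus orbital part right","ORBinf.R","R"
17,"Rolandic operculum left","ROL.L","L"
18,"Rolandic operculum right","ROL.R","R"
19,"Supplementary motor area left","SMA.L","L"
20,"Supplementary motor area right","SMA.R","R"
21,"Olfactory cortex left","OLF.L","L"
22,"Olfactory cortex right","OLF.R","R"
23,"Superior frontal gyrus medial left","SFGmed.L","L"
24,"Superior frontal gyrus medial right","SFGmed.R","R"
25,"Superior frontal gyrus medial orbital left","ORBsupmed.L","L"
26,"Superior frontal gyrus medial orbital right","ORBsupmed.R","R"
27,"Gyrus rectus left","REC.L","L"
28,"Gyrus rectus right","REC.R","R"
29,"Insula left","INS.L","L"
30,"Insula right","INS.R","R"
31,"Anterior cingulate and paracingulate gyri left","ACG.L","L"
32,"Anterior cingulate and paracingulate gyri right","ACG.R","R"
33,"Median cingulate and paracingulate gyri left","DCG.L","L"
34,"Median cingulate and paracingulate gyri right","DCG.R","R"
35,"Posterior cingulate gyrus left","PCG.L","L"
36,"Posterior cingulate gyrus right","PCG.R","R"
37,"Hippocampus left","HIP.L","L"
38,"Hippocampus right","HIP.R","R"
39,"Parahippocampal gyrus left","PHG.L","L"
40,"Parahippocampal gyrus right","PHG.R","R"
41,"Amygdala left","AMYG.L","L"
42,"Amygdala right","AMYG.R","R"
43,"Calcarine fissure and surrounding cortex left","CAL.L","L"
44,"Calcarine fissure and surrounding cortex right","CAL.R","R"
45,"Cuneus left","CUN.L","L"
46,"Cuneus right","CUN.R","R"
47,"Lingual gyrus left","LING.L","L"
48,"Lingual gyrus right","LING.R","R"
49,"Superior occipital gyrus left","SOG.L","L"
50,"Superior occipital gyrus right","SOG.R","R"
51,"Middle occipital gyrus left","MOG.L","L"
52,"Middle occipital gyrus right","MOG.R","R"
53,"Inferior occipital gyrus left","IOG.L","L"
54,"Inferior occipital gyrus right","IOG.R","R"
55,"Fusiform gyrus left","FFG.L","L"
56,"Fusiform gyrus right","FFG.R","R"
57,"Postcentral gyrus left","PoCG.L","L"
58,"Postcentral gyrus right","PoCG.R","R"
59,"Superior parietal gyrus left","SPG.L","L"
60,"Superior parietal gyrus right","SPG.R","R"
61,"Inferior parietal lobule left","IPL.L","L"
62,"Inferior parietal lobule right","IPL.R","R"
63,"Supramarginal gyrus left","SMG.L","L"
64,"Supramarginal gyrus right","SMG.R","R"
65,"Angular gyrus left","ANG.L","L"
66,"Angular gyrus right","ANG.R","R"
67,"Precuneus left","PCUN.L","L"
68,"Precuneus right","PCUN.R","R"
69,"Paracentral lobule left","PCL.L","L"
70,"Paracentral lobule right","PCL.R","R"
71,"Caudate nucleus left","CAU.L","L"
72,"Caudate nucleus right","CAU.R","R"
73,"Putamen left","PUT.L","L"
74,"Putamen right","PUT.R","R"
75,"Pallidum left","PAL.L","L"
76,"Pallidum right","PAL.R","R"
77,"Thalamus left","THA.L","L"
78,"Thalamus right","THA.R","R"
79,"Heschl gyrus left","HES.L","L"
80,"Heschl gyrus right","HES.R","R"
81,"Superior temporal gyrus left","STG.L","L"
82,"Superior temporal gyrus right","STG.R","R"
83,"Temporal pole superior temporal gyrus left","TPOsup.L","L"
84,"Temporal pole superior temporal gyrus right","TPOsup.R","R"
85,"Middle temporal gyrus left","MTG.L","L"
86,"Middle temporal gyrus right","MTG.R","R"
87,"Temporal pole middle temporal gyrus left","TPOmid.L","L"
88,"Temporal pole middle temporal gyrus right","TPOmid.R","R"
89,"Inferior temporal gyrus left","ITG.L","L"
90,"Inferior temporal gyrus right","ITG.R","R"
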