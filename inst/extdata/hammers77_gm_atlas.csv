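# Canonical 77-region grey-matter volume-of-interest list used by this package.
# Derived from the public documentation of the Hammers adult maximum-probability
# brain atlas (n30r83 parcellation): the 83 regions minus corpus callosum,
# lateral ventricles (body and temporal horns) and third ventricle, leaving the
# 77 cortical and subcortical grey-matter VOIs. Integer labels follow the
# n30r83 numbering; names are package-canonical snake_case identifiers.
# volume_mm3 gives plausible adult regional volumes used for volume weighting;
# they are package defaults, not subject-specific measurements.
# composite: one of frontal, parietal, temporal, occipital, insula, limbic,
# basal_ganglia, cerebellum, or none (brainstem).
label,name,composite,volume_mm3
1,hippocampus_R,limbic,3300
2,hippocampus_L,limbic,3200
3,amygdala_R,limbic,1900
4,amygdala_L,limbic,1800
5,ant_temporal_lobe_medial_R,temporal,6200
6,ant_temporal_lobe_medial_L,temporal,6000
7,ant_temporal_lobe_lateral_R,temporal,7200
8,ant_temporal_lobe_lateral_L,temporal,7000
9,parahippocampal_ambient_gyrus_R,limbic,4100
10,parahippocampal_ambient_gyrus_L,limbic,4000
11,superior_temporal_gyrus_post_R,temporal,11200
12,superior_temporal_gyrus_post_L,temporal,11400
13,mid_inf_temporal_gyrus_R,temporal,30500
14,mid_inf_temporal_gyrus_L,temporal,30000
15,fusiform_gyrus_R,temporal,8100
16,fusiform_gyrus_L,temporal,8300
17,cerebellum_R,cerebellum,55500
18,cerebellum_L,cerebellum,55000
19,brainstem,none,28000
20,insula_L,insula,10200
21,insula_R,insula,10400
22,lateral_occipital_lobe_L,occipital,30200
23,lateral_occipital_lobe_R,occipital,29800
24,anterior_cingulate_gyrus_L,limbic,11300
25,anterior_cingulate_gyrus_R,limbic,11500
26,posterior_cingulate_gyrus_L,limbic,10900
27,posterior_cingulate_gyrus_R,limbic,11100
28,middle_frontal_gyrus_L,frontal,38200
29,middle_frontal_gyrus_R,frontal,38600
30,posterior_temporal_lobe_L,temporal,40300
31,posterior_temporal_lobe_R,temporal,39900
32,inferolateral_parietal_lobe_L,parietal,32400
33,inferolateral_parietal_lobe_R,parietal,32000
34,caudate_nucleus_L,basal_ganglia,4100
35,caudate_nucleus_R,basal_ganglia,4200
36,nucleus_accumbens_L,basal_ganglia,620
37,nucleus_accumbens_R,basal_ganglia,600
38,putamen_L,basal_ganglia,4600
39,putamen_R,basal_ganglia,4700
40,thalamus_L,basal_ganglia,7600
41,thalamus_R,basal_ganglia,7500
42,pallidum_L,basal_ganglia,1400
43,pallidum_R,basal_ganglia,1450
50,precentral_gyrus_L,frontal,20300
51,precentral_gyrus_R,frontal,20100
52,straight_gyrus_L,frontal,3500
53,straight_gyrus_R,frontal,3600
54,anterior_orbital_gyrus_L,frontal,3100
55,anterior_orbital_gyrus_R,frontal,3000
56,inferior_frontal_gyrus_L,frontal,17200
57,inferior_frontal_gyrus_R,frontal,17000
58,superior_frontal_gyrus_L,frontal,35400
59,superior_frontal_gyrus_R,frontal,35000
60,postcentral_gyrus_L,parietal,15200
61,postcentral_gyrus_R,parietal,15000
62,superior_parietal_gyrus_L,parietal,20400
63,superior_parietal_gyrus_R,parietal,20000
64,lingual_gyrus_L,occipital,9100
65,lingual_gyrus_R,occipital,9000
66,cuneus_L,occipital,6100
67,cuneus_R,occipital,6000
68,medial_orbital_gyrus_L,frontal,4600
69,medial_orbital_gyrus_R,frontal,4500
70,lateral_orbital_gyrus_L,frontal,2500
71,lateral_orbital_gyrus_R,frontal,2550
72,posterior_orbital_gyrus_L,frontal,3050
73,posterior_orbital_gyrus_R,frontal,3000
74,substantia_nigra_L,basal_ganglia,420
75,substantia_nigra_R,basal_ganglia,400
76,subgenual_frontal_cortex_L,limbic,1000
77,subgenual_frontal_cortex_R,limbic,1050
78,subcallosal_area_L,limbic,700
79,subcallosal_area_R,limbic,720
80,presubgenual_frontal_cortex_L,limbic,820
81,presubgenual_frontal_cortex_R,limbic,800
82,superior_temporal_gyrus_ant_L,temporal,4100
83,superior_temporal_gyrus_ant_R,temporal,4000
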