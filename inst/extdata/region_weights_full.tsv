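dataset	region	clusterIndex	roiMeanT	weightLoocv	weightCross
1	Eyeball_R	1	-4.7459	0.0885	0.0600
1	SMC_B	2	5.2508	-1.0305	-1.0665
1	Eyeball_L	3	-4.7839	0.2405	0.2436
1	Frontal_Inf_Orb_R	4	-3.2028	0.3005	0.3111
1	Frontal_Inf_Orb_L	5	-4.1089	0.4917	0.5112
1	Occipital_Mid_R	6	-4.0079	1.4032	1.4368
1	Caudate_R	7	4.1222	-0.4066	-0.4168
1	Cingulum_Mid_R	8	3.1957	0.1112	0.1258
2	Cerebelum_8_L	1	2.6758	-0.2981	-0.3097
2	Eyeball_R	2	-7.0039	0.1833	0.1897
2	Eyeball_L	3	-7.6689	0.0135	0.0132
2	Lingual_L	4	3.1218	-0.7927	-0.8088
2	Cerebelum_Crus1_R	5	3.2954	-0.5689	-0.5715
2	Cerebelum_4_5_R	6	3.2602	-0.4425	-0.4543
2	SMC_B	7	6.8304	-0.7927	-0.7956
2	Occipital_Mid_L	8	-0.4900	0.2756	0.2758
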