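dataset	region	clusterIndex	roiMeanT	weightLoocv	weightCross
1	SMC_B	2	5.2508	-1.0516	-1.0851
1	Eyeball_L	3	-4.7839	0.3373	0.3374
1	Frontal_Inf_Orb_R	4	-3.2028	0.3499	0.3610
1	Frontal_Inf_Orb_L	5	-4.1089	0.5260	0.5439
1	Occipital_Mid_R	6	-4.0079	1.2911	1.3110
1	Caudate_R	7	4.1222	-0.4244	-0.4327
1	Cingulum_Mid_R	8	3.1957	0.1815	0.1962
2	Cerebelum_8_L	1	2.6758	-0.2988	-0.3062
2	Eyeball_R	2	-7.0039	0.1966	0.2009
2	Lingual_L	4	3.1218	-0.7958	-0.8045
2	Cerebelum_Crus1_R	5	3.2954	-0.5693	-0.5777
2	Cerebelum_4_5_R	6	3.2602	-0.4308	-0.4416
2	SMC_B	7	6.8304	-0.8045	-0.8160
2	Occipital_Mid_L	8	-0.4900	0.2768	0.2771
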