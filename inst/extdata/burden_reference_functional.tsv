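region	n_anomalies	n_subjects	n_low_variance	total_potential	percentage
L_8BM	577	19	377	7163	8.06
R_PFt	533	19	360	6840	7.79
R_V1	540	19	374	7106	7.60
L_9-46d	535	19	379	7201	7.43
L_10v	500	19	378	7182	6.96
R_hippocampus	453	19	370	7030	6.44
L_AAIC	437	19	378	7182	6.08
R_8BL	389	19	378	7182	5.42
R_13l	384	19	374	7106	5.40
L_IFJa	318	19	360	6840	4.65
R_VMV3	327	19	373	7087	4.61
L_PIT	306	19	360	6840	4.47
R_MIP	314	19	371	7049	4.45
R_PHT	290	19	345	6555	4.42
L_IFJp	316	19	376	7144	4.42
L_9p	310	19	371	7049	4.40
R_PIT	303	19	367	6973	4.35
L_s32	289	19	351	6669	4.33
R_p24	304	19	374	7106	4.28
L_PHA1	289	19	357	6783	4.26
L_V4t	290	19	362	6878	4.22
R_PoI2	264	19	334	6346	4.16
R_2	282	19	359	6821	4.13
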