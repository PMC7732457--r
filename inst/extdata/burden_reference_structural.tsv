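region	n_anomalies	n_subjects	n_low_variance	total_potential	percentage
R_8BL	634	21	218	4578	13.85
L_pallidum	592	21	204	4284	13.82
R_pallidum	694	21	249	5229	13.27
R_ventralDC	294	21	112	2352	12.50
R_9m	543	21	211	4431	12.25
R_caudate	362	21	148	3108	11.65
R_10v	714	21	302	6342	11.26
L_ventralDC	203	21	87	1827	11.11
Brain stem	36	21	16	336	10.71
L_putamen	225	21	104	2184	10.30
L_thalamus	240	21	114	2394	10.03
L_8BM	288	21	143	3003	9.59
R_thalamus	207	21	103	2163	9.57
R_8BM	338	21	175	3675	9.20
L_10v	416	21	230	4830	8.61
R_p24	560	21	333	6993	8.01
R_OFC	462	21	276	5796	7.97
R_cerebellum	108	21	65	1365	7.91
R_10pp	301	21	184	3864	7.79
R_a24	498	21	307	6447	7.72
L_caudate	229	21	142	2982	7.68
L_TGd	170	21	106	2226	7.64
R_accumbens	417	21	261	5481	7.61
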