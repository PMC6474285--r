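# Canonical 1H chemical-shift fixture for the packaged metabolite libraries.
# Peak centers (ppm, 600 MHz solution state) are rounded literature consensus
# values of the kind tabulated in public metabolomics databases; relative
# heights are coarse proton-count proxies. ref_conc is a synthetic reference
# concentration (arbitrary units) chosen once for the simulator; neither
# heights nor ref_conc are measured values. linewidth is the Lorentzian
# half-width gamma in ppm. One row per peak. Version 1, frozen.
tissue	metabolite	ref_conc	linewidth	center	height
serum	Leucine	0.8	0.0015	0.96	6
serum	Leucine	0.8	0.0015	1.71	3
serum	Valine	0.6	0.0015	0.99	3
serum	Valine	0.6	0.0015	1.04	3
serum	Valine	0.6	0.0015	2.27	1
serum	Isoleucine	0.4	0.0015	0.94	3
serum	Isoleucine	0.4	0.0015	1.01	3
serum	3-Hydroxybutyrate	0.5	0.0015	1.20	3
serum	3-Hydroxybutyrate	0.5	0.0015	2.31	1
serum	3-Hydroxybutyrate	0.5	0.0015	4.13	1
serum	Methylmalonate	0.3	0.0015	1.24	3
serum	Methylmalonate	0.3	0.0015	3.17	1
serum	Lactate	2.5	0.0015	1.33	3
serum	Lactate	2.5	0.0015	4.11	1
serum	Alanine	1.0	0.0015	1.48	3
serum	Alanine	1.0	0.0015	3.78	1
serum	Lysine	0.6	0.0015	1.72	2
serum	Lysine	0.6	0.0015	1.91	2
serum	Lysine	0.6	0.0015	3.03	2
serum	Gamma-aminobutyric acid	0.4	0.0015	1.89	2
serum	Gamma-aminobutyric acid	0.4	0.0015	2.30	2
serum	Gamma-aminobutyric acid	0.4	0.0015	3.01	2
serum	Acetate	0.8	0.0015	1.92	3
serum	Glutamate	0.9	0.0015	2.08	2
serum	Glutamate	0.9	0.0015	2.34	2
serum	Glutamate	0.9	0.0015	3.75	1
serum	Pyruvate	0.4	0.0015	2.37	3
serum	Succinate	0.5	0.0015	2.41	4
serum	Glutamine	0.9	0.0015	2.14	2
serum	Glutamine	0.9	0.0015	2.45	2
serum	Glutamine	0.9	0.0015	3.77	1
serum	Citrate	0.6	0.0015	2.54	2
serum	Citrate	0.6	0.0015	2.66	2
serum	Creatine	0.7	0.0015	3.03	3
serum	Creatine	0.7	0.0015	3.93	2
serum	Ethanolamine	0.3	0.0015	3.15	2
serum	Ethanolamine	0.3	0.0015	3.82	2
serum	Choline	0.5	0.0015	3.20	9
serum	Choline	0.5	0.0015	3.52	2
serum	Choline	0.5	0.0015	4.06	2
serum	Glucose	3.0	0.0015	3.24	1
serum	Glucose	3.0	0.0015	3.41	2
serum	Glucose	3.0	0.0015	3.47	2
serum	Glucose	3.0	0.0015	3.72	2
serum	Glucose	3.0	0.0015	3.89	1
serum	Glucose	3.0	0.0015	5.23	0.4
serum	Glycine	0.8	0.0015	3.56	2
serum	Glycerol	0.6	0.0015	3.55	2
serum	Glycerol	0.6	0.0015	3.64	2
serum	Glycerol	0.6	0.0015	3.78	1
brain	Leucine	0.6	0.0015	0.96	6
brain	Leucine	0.6	0.0015	1.71	3
brain	Valine	0.4	0.0015	0.99	3
brain	Valine	0.4	0.0015	1.04	3
brain	Isoleucine	0.3	0.0015	0.94	3
brain	Isoleucine	0.3	0.0015	1.01	3
brain	3-Hydroxybutyrate	0.3	0.0015	1.20	3
brain	3-Hydroxybutyrate	0.3	0.0015	2.31	1
brain	Methylmalonate	0.2	0.0015	1.24	3
brain	Methylmalonate	0.2	0.0015	3.17	1
brain	Alanine	0.8	0.0015	1.48	3
brain	Alanine	0.8	0.0015	3.78	1
brain	Lysine	0.5	0.0015	1.72	2
brain	Lysine	0.5	0.0015	1.91	2
brain	Lysine	0.5	0.0015	3.03	2
brain	Gamma-aminobutyric acid	1.2	0.0015	1.89	2
brain	Gamma-aminobutyric acid	1.2	0.0015	2.30	2
brain	Gamma-aminobutyric acid	1.2	0.0015	3.01	2
brain	Acetate	0.5	0.0015	1.92	3
brain	N-Acetylaspartate	2.0	0.0015	2.01	3
brain	N-Acetylaspartate	2.0	0.0015	2.49	1
brain	N-Acetylaspartate	2.0	0.0015	2.68	1
brain	N-Acetylaspartate	2.0	0.0015	4.38	1
brain	Glutamate	2.5	0.0015	2.08	2
brain	Glutamate	2.5	0.0015	2.34	2
brain	Glutamate	2.5	0.0015	3.75	1
brain	N-Acetylglutamate	0.4	0.0015	2.04	3
brain	N-Acetylglutamate	0.4	0.0015	2.23	2
brain	Succinate	0.4	0.0015	2.41	4
brain	Glutamine	1.5	0.0015	2.14	2
brain	Glutamine	1.5	0.0015	2.45	2
brain	Glutamine	1.5	0.0015	3.77	1
brain	Citrate	0.4	0.0015	2.54	2
brain	Citrate	0.4	0.0015	2.66	2
brain	Glutathione	0.8	0.0015	2.16	2
brain	Glutathione	0.8	0.0015	2.55	2
brain	Glutathione	0.8	0.0015	2.95	2
brain	Glutathione	0.8	0.0015	3.77	1
brain	Methionine	0.3	0.0015	2.13	3
brain	Methionine	0.3	0.0015	2.64	2
brain	Aspartate	1.0	0.0015	2.68	1
brain	Aspartate	1.0	0.0015	2.80	1
brain	Aspartate	1.0	0.0015	3.89	1
brain	Trimethylamine	0.2	0.0015	2.89	9
brain	Creatine/Creatine phosphate	2.2	0.0015	3.03	3
brain	Creatine/Creatine phosphate	2.2	0.0015	3.93	2
brain	Malonate	0.3	0.0015	3.11	2
brain	Ethanolamine	0.4	0.0015	3.15	2
brain	Ethanolamine	0.4	0.0015	3.82	2
brain	Choline	0.5	0.0015	3.20	9
brain	Choline	0.5	0.0015	3.52	2
brain	Choline	0.5	0.0015	4.06	2
brain	Trimethylamine-N-oxide	0.4	0.0015	3.26	9
brain	Betaine	0.4	0.0015	3.27	9
brain	Betaine	0.4	0.0015	3.90	2
brain	Taurine	1.8	0.0015	3.25	2
brain	Taurine	1.8	0.0015	3.42	2
brain	Glucose	1.5	0.0015	3.24	1
brain	Glucose	1.5	0.0015	3.41	2
brain	Glucose	1.5	0.0015	3.47	2
brain	Glucose	1.5	0.0015	3.72	2
brain	Glucose	1.5	0.0015	3.89	1
brain	Glucose	1.5	0.0015	5.23	0.4
brain	Myo-inositol	1.6	0.0015	3.28	2
brain	Myo-inositol	1.6	0.0015	3.53	2
brain	Myo-inositol	1.6	0.0015	3.62	2
brain	Myo-inositol	1.6	0.0015	4.06	1
brain	Glycine	1.0	0.0015	3.56	2
brain	Glycerol	0.5	0.0015	3.55	2
brain	Glycerol	0.5	0.0015	3.64	2
brain	Glycerol	0.5	0.0015	3.78	1
brain	Threonine	0.4	0.0015	1.32	3
brain	Threonine	0.4	0.0015	3.58	1
brain	Threonine	0.4	0.0015	4.25	1
brain	Serine	0.6	0.0015	3.84	1
brain	Serine	0.6	0.0015	3.96	2
brain	Ascorbate	0.4	0.0015	3.73	1
brain	Ascorbate	0.4	0.0015	4.01	1
brain	Ascorbate	0.4	0.0015	4.52	1
brain	Lactate	1.8	0.0015	1.33	3
brain	Lactate	1.8	0.0015	4.11	1
brain	O-phosphocholine	0.6	0.0015	3.22	9
brain	O-phosphocholine	0.6	0.0015	3.59	2
brain	O-phosphocholine	0.6	0.0015	4.17	2
brain	Inosine	0.4	0.0015	6.10	1
brain	Inosine	0.4	0.0015	8.23	1
brain	Inosine	0.4	0.0015	8.34	1
brain	UDP-glucose	0.3	0.0015	5.60	1
brain	UDP-glucose	0.3	0.0015	5.98	1
brain	UDP-glucose	0.3	0.0015	7.95	1
brain	Uracil	0.2	0.0015	5.80	1
brain	Uracil	0.2	0.0015	7.54	1
brain	Uridine	0.2	0.0015	5.90	1
brain	Uridine	0.2	0.0015	7.87	1
brain	Cytidine	0.2	0.0015	6.06	1
brain	Cytidine	0.2	0.0015	7.84	1
brain	ADP	0.5	0.0015	6.15	1
brain	ADP	0.5	0.0015	8.27	1
brain	ADP	0.5	0.0015	8.53	1
brain	AMP	0.4	0.0015	6.14	1
brain	AMP	0.4	0.0015	8.27	1
brain	AMP	0.4	0.0015	8.61	1
brain	Fumarate	0.2	0.0015	6.52	2
brain	Tyrosine	0.3	0.0015	6.90	2
brain	Tyrosine	0.3	0.0015	7.19	2
brain	Anserine	0.3	0.0015	7.07	1
brain	Anserine	0.3	0.0015	8.07	1
brain	Phenylalanine	0.3	0.0015	7.33	2
brain	Phenylalanine	0.3	0.0015	7.38	2
brain	Phenylalanine	0.3	0.0015	7.43	1
brain	Nicotinurate	0.2	0.0015	7.60	1
brain	Nicotinurate	0.2	0.0015	8.25	1
brain	Nicotinurate	0.2	0.0015	8.71	1
brain	Nicotinurate	0.2	0.0015	8.94	1
brain	Xanthine	0.2	0.0015	7.89	1
brain	Guanosine	0.2	0.0015	5.92	1
brain	Guanosine	0.2	0.0015	8.00	1
brain	Carnosine	0.3	0.0015	7.09	1
brain	Carnosine	0.3	0.0015	8.12	1
brain	Hypoxanthine	0.2	0.0015	8.19	1
brain	Hypoxanthine	0.2	0.0015	8.21	1
brain	Oxypurinol	0.2	0.0015	8.24	1
brain	Adenosine	0.3	0.0015	6.09	1
brain	Adenosine	0.3	0.0015	8.24	1
brain	Adenosine	0.3	0.0015	8.34	1
brain	NADH	0.3	0.0015	6.96	1
brain	NADH	0.3	0.0015	8.25	1
brain	NADH	0.3	0.0015	8.48	1
brain	Formate	0.2	0.0015	8.46	1
brain	ATP	0.8	0.0015	6.15	1
brain	ATP	0.8	0.0015	8.26	1
brain	ATP	0.8	0.0015	8.54	1
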