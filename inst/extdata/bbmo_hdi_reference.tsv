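# Published monthly HDI values for the 17 dominant taxonomic groups of the
# two-year (June 2011 - June 2013) size-fractionated survey at the Blanes Bay
# Microbial Observatory. Categories: A = enriched in small size-fractions,
# B = enriched in small but depleted in the smallest, C = no size-fraction
# enrichment, D = enriched in large size-fractions.
# published_average is the table's printed one-decimal annual row average.
category	group	January	February	March	April	May	June	July	August	September	October	November	December	published_average
A	SAR116 clade (Alphaproteobacteria)	12.38	4.35	9.59	7.69	7.23	6.07	4.83	4.17	7.8	6.15	5.47	5.12	6.7
A	SAR11 clade (Alphaproteobacteria)	5.56	7.17	9.41	1.34	7.15	6.2	3.13	9.34	16.31	5.08	7.55	3.9	6.8
B	Synechococcus (Cyanobacteria)	2.1	3.43	2.26	1.79	3.73	1.35	2.22	1.8	2.78	1.64	2.32	1.42	2.2
C	Actinobacteria	5.27	2.35	1.76	7.17	3.07	2.6	3.24	2.61	1.8	3.39	3.23	1.4	3.2
C	Deferribacteres	6.27	1.63	4.78	3.75	9.13	8.37	8.46	5.21	4.47	3.44	4.79	2.69	5.3
C	Oceanospirillales (Gammaproteobacteria)	2.01	1.03	2.03	3	8.74	1.14	2.34	3.54	1.14	1.79	1.52	1.3	2.5
D	Rhodobacterales (Alphaproteobacteria)	6.18	2.01	1.15	3.37	1.81	3.49	3.15	1	2.61	2.25	2.84	1.89	2.6
D	Alteromonadales (Gammaproteobacteria)	2.57	2.39	3.19	2.62	3.12	3.46	3.45	3.92	1.92	2	5.63	3.23	3.1
D	Cytophagia (Bacteroidetes)	7.23	1.72	4.03	5.77	3.83	4.75	7.02	8.85	3.03	2.51	5.15	4.04	4.8
D	Vibrionales (Gammaproteobacteria)	6.75	8.6	2.09	4.21	4.57	3.38	13.47	6.5	3.68	2.03	5.21	4.78	5.4
D	Sphingobacteriia (Bacteroidetes)	2.18	2.24	4.46	9.59	2.89	3.38	4.96	7.24	2.55	1.37	3.38	2.72	3.9
D	Firmicutes	1.28	1.71	5.11	5.93	2.14	5.02	4.68	3.92	2.24	1.65	3.5	1.9	3.3
D	Planctomycetes	3.67	3.37	7.17	1.84	5.66	17.97	17.44	2.76	4.02	4.18	3.93	2.16	6.2
D	Verrucomicrobia	1.99	1.96	3.85	4.54	1.82	1.37	2.79	1.02	1.73	1.02	4.17	1.04	2.3
D	Rhizobiales (Alphaproteobacteria)	1.11	3.09	4.05	2.52	2.53	2.94	3.55	1.8	2.01	3.99	2.01	1.37	2.6
D	Deltaproteobacteria	1.6	4.9	1.77	2.03	5.61	4.21	8.92	2.46	2.86	3.1	6.47	4.49	4
D	Flavobacteria (Bacteroidetes)	1.05	1.4	1.71	4.37	1.43	1.62	3.06	2.09	0.93	0.7	2.65	1	1.8
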