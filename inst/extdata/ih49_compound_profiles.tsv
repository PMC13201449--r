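mol_id	compound	aspl	betweenness	closeness	degree
MOL1	cerevisterol	2.595129376	0.076196405	0.385337243	109
MOL2	(22E,24R)-ergosta-7,22-diene-3b,5a,6b,9a-tetrol	2.598173516	0.087483702	0.384885764	108
MOL3	withanolide	2.601217656	0.092902934	0.384435342	107
MOL4	Inonoterpene A	2.604261796	0.04795027	0.383985973	106
MOL5	Polyporusterone D	2.607305936	0.068780971	0.383537653	105
MOL6	Polyporusterone B	2.610350076	0.077894162	0.383090379	104
MOL7	yakuchinone A	2.613394216	0.127866504	0.382644147	103
MOL8	1,2-benzenedicarboxylic acid mono (2-ethylhexyl) ester	2.616438356	0.124577165	0.382198953	102
MOL9	malvalic acid	2.616438356	0.048061086	0.382198953	102
MOL10	ricinoleic acid	2.616438356	0.044292473	0.382198953	102
MOL11	ergosterol-5,8-peroxide	2.628614916	0.064080037	0.380428489	98
MOL12	11-hydroxy-9-tridecenoic acid	2.628614916	0.060111554	0.380428489	98
MOL13	5a,8a-epidioxy-(22E,24R)-ergosta-6,22-dien-3b-ol	2.643835616	0.059180085	0.378238342	93
MOL14	Abrisapogenol I	2.671232877	0.02023839	0.374358974	84
MOL15	hexadecanoic acid	2.674277017	0.073920432	0.37393284	83
MOL16	Maslinic acid	2.695585997	0.020248586	0.370976849	76
MOL17	Asiatic acid	2.713850837	0.015973196	0.36848009	70
MOL18	Bassic acid	2.719939117	0.017543087	0.367655288	68
MOL19	9-hexadecenoic acid methyl ester	2.722983257	0.025637785	0.367244271	67
MOL20	tetrahydrocortisone	2.741248097	0.039336431	0.364797335	61
MOL21	inonophenol C	2.750380518	0.059996849	0.363586054	58
MOL22	Hispolon	2.771689498	0.034947073	0.360790774	51
MOL23	4-(3',4'-dihydroxyphenyl)-2-butanone	2.771689498	0.043511895	0.360790774	51
MOL24	4-(3,4-Dihydroxyphenyl)-3-buten-2-one	2.792998478	0.030797079	0.358038147	44
MOL25	(E)-labda-8 (17),12-diene-15,16-dial	2.802130898	0.033982077	0.356871266	41
MOL26	Methyl-hexadecanoic acid	2.811263318	0.016813379	0.355711965	38
MOL27	ciclesonide	2.823439878	0.020150711	0.354177898	34
MOL28	3a,7a,12b-trihydroxy-5b-cholanoic acid	2.829528158	0.004075749	0.353415815	32
MOL29	cinnamic acid	2.832572298	0.016523035	0.353036002	31
MOL30	protocatechuic acid	2.844748858	0.018555005	0.35152488	27
MOL31	Inotilone	2.847792998	0.022108209	0.351149118	26
MOL32	ononin	2.847792998	0.024659903	0.351149118	26
MOL33	Inonotusin B	2.850837139	0.007145771	0.350774159	25
MOL34	phenylalaninopine	2.866057839	0.028148656	0.348911312	20
MOL35	3,4-Dihydroxybenzaldehyde	2.872146119	0.006809176	0.348171701	18
MOL36	1-hexanol	2.875190259	0.005580209	0.34780307	17
MOL37	methyl 5-(3,4-dihydroxyphenyl)-3-hydroxypenta-2,4-dienoate	2.878234399	0.005988319	0.347435219	16
MOL38	Hexadecenoic acid	2.887366819	0.001070746	0.346336321	13
MOL39	Inonotusin A	2.899543379	0.008687014	0.34488189	9
MOL40	hispinine	2.902587519	0.000858	0.344520189	8
MOL41	Benzaldehyde	2.911719939	0.001204594	0.343439624	5
MOL42	Phaeolschidin E	2.911719939	0.00624098	0.343439624	5
MOL43	Bis-noryangonin	2.914764079	0.003216263	0.34308094	4
MOL44	Hispidin	2.914764079	0.001636819	0.34308094	4
MOL45	Phellibaumin A	2.917808219	0.003061029	0.342723005	3
MOL46	Phelligridin C	2.917808219	0.000418	0.342723005	3
MOL47	Phelligridin C'	2.917808219	0.000418	0.342723005	3
MOL48	D-arabitol	2.917808219	0.003694769	0.342723005	3
MOL49	Phelligridin J	2.920852359	0.000179	0.342365816	2
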