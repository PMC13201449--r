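rt_min	mz	formula	frag1	frag2	frag3	compound
9.79	177.05571	C10H10O3	121.0491	135.044	149.06	Osmundacetone
11.68	217.05063	C12H10O4	128.0341	173.0924	181.071	Inotilone
13.00	489.08271	C26H18O10	191.0345	245.0452	269.0462	3,14'-bihispidinyl
17.81	379.04594	C20H12O8	217.1191	245.113	159.1301	Phelligridin D
20.52	543.12967	C30H24O10	238.0821	287.5542	296.1048	Phaeolschidin A ion
20.52	363.05102	C20H12O7	112.9844	135.044	155.1068	Phaeolschidin C
22.18	503.09837	C27H20O10	213.0549	245.0449	257.0458	SCHEMBL8676491
28.36	559.16097	C31H28O10	245.0454	269.1191	313.1084	Phaeolschidin B
32.08	485.32724	C30H46O5	290.2484	318.2792	362.269	Abrisapogenol I
32.08	485.32724	C30H46O5	325.2532	359.6371	431.3057	Bassic acid
32.75	363.21769	C21H32O5	217.0134	241.1269	269.0096	Tetrahydrocortisone
32.93	295.22786	C18H32O3	237.186	267.9725	277.2177	Hydroxy-octadecadienoic acid
33.75	297.24350	C18H34O3	115.0025	133.013	181.071	Ricinoleic acid
34.75	293.21221	C18H30O3	249.2224	275.2033	293.2128	Hydroxy-octadecatrienoic acid
42.48	253.21730	C16H30O2	209.1544	219.5377	253.1205	Hexadecenoic acid
43.48	279.23295	C18H32O2	225.9843	244.0614	262.073	Hexadecanoic acid
46.46	281.24860	C18H34O2	243.7909	257.8292	281.2488	Octadecenoic acid
47.48	281.24860	C18H34O2	129.091	139.3854	183.1386	Oleic acid
50.80	283.26425	C18H36O2	219.8441	239.1652	265.1448	Octadecanoic acid
53.41	355.10345	C16H20O9	112.9843	171.0054	241.1206	Gentiopicroside
53.41	391.30063	C28H40O	170.1544	229.1555	271.1667	(22E,24x)-Ergosta-4,6,8,22-tetraen-3-one
54.15	391.30063	C28H40O	229.1555	271.1667	301.1781	Ergosta-4,6,8 (14),22-tetraen-3-one
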