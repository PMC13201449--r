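ligand	receptor	pdb_id	energy_kcal_mol
withanolide	EGFR	1M14	-9.3
withanolide	BCL2	1G5M	-9.1
withanolide	STAT3	6NJS	-8.8
withanolide	AKT1	1H10	-8.2
withanolide	CTNNB1	2Z6H	-7.9
cerevisterol	AKT1	1H10	-7.4
cerevisterol	CTNNB1	2Z6H	-6.8
cerevisterol	EGFR	1M14	-7.1
cerevisterol	STAT3	6NJS	-6.2
cerevisterol	BCL2	1G5M	-6.6
ergostatetrol	AKT1	1H10	-6.9
ergostatetrol	CTNNB1	2Z6H	-6.1
ergostatetrol	EGFR	1M14	-6.4
ergostatetrol	STAT3	6NJS	-5.8
ergostatetrol	BCL2	1G5M	-5.5
inonoterpene_A	AKT1	1H10	-6.3
inonoterpene_A	CTNNB1	2Z6H	-5.7
inonoterpene_A	EGFR	1M14	-5.9
inonoterpene_A	STAT3	6NJS	-5.2
inonoterpene_A	BCL2	1G5M	-4.8
polyporusterone_D	AKT1	1H10	-6.0
polyporusterone_D	CTNNB1	2Z6H	-5.4
polyporusterone_D	EGFR	1M14	-5.6
polyporusterone_D	STAT3	6NJS	-5.0
polyporusterone_D	BCL2	1G5M	-4.6
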