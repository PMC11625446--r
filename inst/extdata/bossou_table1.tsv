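individual	sex	age_years	sampled	n_sequences	n_elements	n_action_types	nuts_cracked
Fanle	F	14	TRUE	21	1368	34	85
Flanle	M	4	TRUE	35	453	59	1
Foaf	M	31	TRUE	8	299	18	10
Jeje	M	14	TRUE	18	1373	36	39
Jire	F	53	TRUE	12	482	33	22
Joya	F	7	TRUE	39	1178	55	22
Peley	M	13	TRUE	15	1168	44	45
Tua	M	54	TRUE	15	1940	43	79
Velu	F	52	FALSE	2	16	12	0
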