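individual	sex	age_class	max_distance	censored	preferred_model	transition_point	per_nut_mean	per_nut_se	nuts_cracked
Fanle	F	Adult	17	FALSE	power_law	NA	13.9	0.4	85
Flanle	M	Infant	100	TRUE	composite	2	48	NA	1
Foaf	M	Adult	9	FALSE	exponential	NA	31.2	1.8	10
Jeje	M	Adult	22	FALSE	composite	4	29.4	0.9	39
Jire	F	Adult	11	FALSE	power_law	NA	16.0	0.9	22
Joya	F	Juvenile	21	FALSE	composite	8	36	1.3	22
Peley	M	Adult	42	FALSE	composite	2	21.7	0.7	45
Tua	M	Adult	20	FALSE	composite	7	22.4	0.5	79
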