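individual	max_element_distance	model	K	AICc	dAICc	weight	cum_weight	LL
Fanle	16	composite	5	-70.5	0.0	0.93	0.93	43.6
Fanle	16	power_law	3	-65.2	5.3	0.07	1.00	36.7
Fanle	16	exponential	3	-47.2	23.3	0.00	1.00	27.7
Flanle	9	power_law	3	-18.5	0.0	0.98	0.98	15.3
Flanle	9	exponential	3	-10.3	8.2	0.02	1.00	11.2
Flanle	9	composite	5	0.8	19.4	0.00	1.00	19.6
Foaf	10	exponential	5	-36.7	0.0	1.00	1.00	23.8
Foaf	10	power_law	3	-22.7	14.0	0.00	1.00	16.8
Foaf	10	composite	3	-14.1	22.6	0.00	1.00	22.1
Jeje	11	composite	5	-43.0	0.0	0.72	0.72	34.0
Jeje	11	exponential	3	-41.2	1.8	0.28	1.00	25.6
Jeje	11	power_law	3	-23.0	20.0	0.00	1.00	16.5
Jire	9	power_law	3	-22.7	0.0	0.54	0.54	17.4
Jire	9	exponential	3	-22.4	0.3	0.46	1.00	17.2
Jire	9	composite	5	10.7	12.0	0.00	1.00	25.4
Joya	9	power_law	3	-26.5	0.0	1.00	1.00	19.2
Joya	9	exponential	3	-15.0	11.5	0.00	1.00	13.5
Joya	9	composite	5	-2.3	24.2	0.00	1.00	21.2
Peley	26	composite	5	-121.8	0.0	0.80	0.80	67.5
Peley	26	power_law	3	-119.1	2.7	0.20	1.00	63.1
Peley	26	exponential	3	-80.0	41.8	0.00	1.00	43.6
Tua	16	composite	5	-92.2	0.0	1.00	1.00	54.5
Tua	16	exponential	3	-70.7	21.5	0.00	1.00	39.4
Tua	16	power_law	3	-49.0	43.2	0.00	1.00	28.6
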