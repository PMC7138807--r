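sample_id	pH	AK	OC	TN	AN	AP	latitude	longitude	PRE	TEM	soil_type
1	7.68	117.10	18.26	0.78	43.75	61.98	18.65	109.67	2162.8	24.8	sandy clay loam
2	5.46	167.70	26.40	1.06	103.25	15.83	25.00	101.51	937.2	16.2	clay loam
3	7.93	125.20	14.87	0.68	35.00	17.44	27.92	112.75	1377.0	17.4	loamy clay
4	8.00	116.10	10.42	0.44	19.25	8.30	29.23	120.05	1386.6	17.7	sandy loam
5	7.96	145.40	29.72	0.96	98.00	30.48	29.52	106.66	1108.0	18.4	sandy loam
6	8.39	55.10	3.16	0.44	3.50	3.39	31.88	106.16	1013.5	16.6	loamy clay
7	5.23	135.30	13.62	0.56	94.50	21.82	33.28	114.30	863.1	14.8	clay loam
8	8.33	198.20	16.49	0.84	31.50	14.17	34.36	109.12	569.4	13.8	clay loam
9	8.65	234.70	16.75	0.50	35.00	17.03	35.15	111.23	519.2	13.2	silty clay loam
10	7.87	86.50	14.86	0.56	87.50	9.45	35.95	116.57	614.3	14.0	clay loam
11	8.72	208.30	11.67	0.44	49.00	4.92	36.25	106.39	425.5	6.9	clay loam
12	8.74	102.80	5.86	0.16	5.25	4.45	36.59	107.27	409.5	9.2	silty clay loam
13	6.37	288.20	15.25	0.62	31.50	87.36	36.64	119.41	546.5	12.8	loamy clay
14	5.83	135.40	37.52	1.24	63.00	175.37	37.36	114.79	478.2	13.2	sandy loam
15	8.76	207.30	13.73	0.50	5.25	38.06	38.45	77.25	61.3	12.0	sandy loam
16	8.50	80.70	23.17	0.68	29.75	127.64	39.52	112.53	407.3	6.1	sandy loam
17	8.86	248.90	18.94	0.78	87.50	52.70	39.88	117.73	623.8	11.9	clay loam
18	7.04	105.00	10.06	0.56	21.00	14.10	39.94	121.52	617.5	9.9	sandy clay loam
19	8.45	143.40	8.81	0.40	175.00	57.88	40.75	111.97	396.5	7.3	loamy clay
20	8.04	323.00	34.16	1.00	47.25	56.16	43.87	126.75	580.0	5.0	loamy clay
21	8.18	144.40	26.59	1.00	66.50	28.88	46.51	124.96	434.6	3.8	sandy loam
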