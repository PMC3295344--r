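cause	pollutant	city	er	lo	hi	published_p
total	o3_8h	guangzhou	0.64	0.42	0.86	0.432
total	o3_8h	foshan	0.36	-0.06	0.78	0.432
total	o3_8h	zhongshan	0.61	0.22	1.00	0.432
total	o3_8h	zhuhai	0.22	-0.36	0.81	0.432
total	no2	guangzhou	1.66	1.28	2.05	0.555
total	no2	foshan	1.87	1.40	2.35	0.555
total	no2	zhongshan	1.22	0.44	2.01	0.555
total	no2	zhuhai	1.39	-0.09	2.89	0.555
total	pm10	guangzhou	0.74	0.53	0.95	0.351
total	pm10	foshan	0.50	0.31	0.69	0.351
total	pm10	zhongshan	0.44	-0.02	0.91	0.351
total	pm10	zhuhai	0.37	-0.97	1.73	0.351
cvd	o3_8h	guangzhou	0.98	0.61	1.35	0.144
cvd	o3_8h	foshan	0.43	-0.25	1.12	0.144
cvd	o3_8h	zhongshan	0.77	0.19	1.35	0.144
cvd	o3_8h	zhuhai	-0.08	-1.00	0.85	0.144
cvd	no2	guangzhou	1.92	1.29	2.57	0.426
cvd	no2	foshan	2.35	1.59	3.13	0.426
cvd	no2	zhongshan	1.19	0.05	2.34	0.426
cvd	no2	zhuhai	2.22	-0.09	4.58	0.426
cvd	pm10	guangzhou	0.92	0.58	1.26	0.611
cvd	pm10	foshan	0.71	0.40	1.01	0.611
cvd	pm10	zhongshan	0.45	-0.23	1.14	0.611
cvd	pm10	zhuhai	0.47	-1.62	2.60	0.611
resp	o3_8h	guangzhou	0.89	0.38	1.41	0.631
resp	o3_8h	foshan	0.46	-0.43	1.36	0.631
resp	o3_8h	zhongshan	0.61	-0.32	1.55	0.631
resp	o3_8h	zhuhai	1.61	-0.05	3.30	0.631
resp	no2	guangzhou	2.99	2.13	3.86	0.147
resp	no2	foshan	1.60	0.60	2.61	0.147
resp	no2	zhongshan	3.44	1.67	5.25	0.147
resp	no2	zhuhai	2.46	-1.59	6.67	0.147
resp	pm10	guangzhou	1.20	0.72	1.68	0.003
resp	pm10	foshan	0.09	-0.32	0.50	0.003
resp	pm10	zhongshan	1.00	-0.09	2.10	0.003
resp	pm10	zhuhai	2.82	-0.96	6.75	0.003
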