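cause	model	stratum	er	lo	hi
total	single	peak	0.65	0.27	1.02
total	single	nonpeak	0.92	0.69	1.16
total	pm10_adjusted	peak	0.77	0.32	1.22
total	pm10_adjusted	nonpeak	0.64	0.39	0.89
cvd	single	peak	0.96	0.35	1.58
cvd	single	nonpeak	1.06	0.69	1.44
cvd	pm10_adjusted	peak	1.33	0.59	2.08
cvd	pm10_adjusted	nonpeak	0.67	0.27	1.07
resp	single	peak	0.24	-0.63	1.13
resp	single	nonpeak	2.00	1.47	2.53
resp	pm10_adjusted	peak	0.08	-0.98	1.16
resp	pm10_adjusted	nonpeak	1.62	1.05	2.20
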