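server_id	requests	predictions	MTSA	MTDV	MAD	ART	MTBF	MTTR
103	3.19E+05	6.70E+05	7.58E-01	1.32E-03	2.13E+00	1.61E+00	4.58E+06	0.00E+00
106	3.12E+05	4.07E+06	8.59E-02	9.42E-04	1.34E+01	1.15E+00	4.58E+06	0.00E+00
107	2.95E+05	1.14E+06	2.85E+02	1.00E+00	4.27E+00	1.22E+03	4.62E+05	2.23E+05
108	1.23E+05	0.00E+00	NA	3.03E-02	0.00E+00	3.63E+01	4.58E+06	0.00E+00
111	3.11E+05	5.59E+05	3.55E+02	6.48E-01	2.27E+00	8.06E+02	5.19E+05	2.12E+04
114	3.19E+05	4.78E+06	1.21E-01	1.48E-03	1.51E+01	1.82E+00	4.58E+06	0.00E+00
116	2.29E+05	2.31E+06	3.83E+02	7.55E+00	2.35E+01	9.01E+03	8.11E+04	4.65E+05
117	3.19E+05	7.13E+06	1.29E-01	2.38E-03	2.25E+01	2.90E+00	4.58E+06	0.00E+00
120	2.91E+05	2.74E+07	1.37E-02	1.15E-03	1.01E+02	1.39E+00	4.58E+06	0.00E+00
121	3.19E+05	3.30E+06	1.18E-01	9.96E-04	1.04E+01	1.22E+00	4.58E+06	0.00E+00
122	3.16E+05	4.42E+06	7.23E-02	8.58E-04	1.48E+01	1.07E+00	4.58E+06	0.00E+00
124	4.98E+04	2.98E+04	1.55E+01	4.49E-02	3.29E+00	5.14E+01	1.17E+06	6.09E+04
126	4.98E+04	3.22E+04	1.50E+01	5.00E-02	3.69E+00	5.58E+01	5.86E+05	8.98E+04
127	3.19E+05	2.79E+06	4.20E-01	3.07E-03	8.90E+00	3.74E+00	4.58E+06	0.00E+00
128	1.87E+05	8.57E+05	5.44E+02	6.35E+00	1.38E+01	7.52E+03	1.73E+05	1.47E+05
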