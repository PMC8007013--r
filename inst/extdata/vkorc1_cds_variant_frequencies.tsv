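variant	class	warfarin	Overall	African	Latino	Ashkenazi Jewish	East Asian	Finnish	Non-Finnish European	Other groups	South Asian
106GT	missense	Resistance	0.00241	0	0.00166	0.03857	0	5.6E-05	0.00069	0.00460	0.00091
203AG	missense		0.00044	0	0	0	0.00571	0	8.8E-06	0.00016	9.8E-05
352GC	missense		0.00036	0	0	0	0.00359	0	0	0.00016	0.00078
202CT	missense		0.00036	6.2E-05	0	0	0	0.00083	0.00059	0.00065	0
79CG	missense		0.00031	0	0	0	0	0	6.8E-05	0	0.00217
196GA	missense		0.00020	0.00265	0.00014	0	0	0	0	0	3.3E-05
427GA	missense		0.00017	0	0.00116	0	0	0	8.8E-06	0.00016	0
390TG	missense		0.00012	0	0	0	0.00169	0	0	0	0
157CA	missense		0.00011	0	0	0	0.00139	0	0	0.00017	0
163TC	missense		1.0E-04	0	0.00067	0	0	0	0	0.00017	0
358CT	synonymous	Resistance	0.01558	0.19520	0.01186	0.00626	0.00011	0	0.00170	0.01044	0.00065
36GA	synonymous	Resistance*	0.01511	0.00210	0.01583	0.02262	5.6E-05	0.07348	0.01171	0.02296	0.00200
129CT	synonymous		0.003643	0.00115	0.00093	0.00115	0	0.00504	0.00567	0.00415	0.00282
54GT	synonymous		7.7E-05	0	0.00030	0	0.00023	0	2.9E-05	0	3.3E-05
234AG	synonymous		3.6E-05	0	0.00012	0	0	0	3.5E-05	0.00016	0
54GC	synonymous		2.6E-05	7.1E-05	3.0E-05	0	0	0	2.9E-05	0	3.3E-05
18GA	synonymous		1.7E-05	0	9.0E-05	0	0	0	9.8E-06	0	0
111GA	synonymous		1.7E-05	0	3.0E-05	0	0.00011	0	9.8E-06	0	0
72CT	synonymous		1.7E-05	0	0	0	0	0	3.9E-05	0	0
186TG	synonymous		1.6E-05	0	0	0	0	0	3.5E-05	0	0
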