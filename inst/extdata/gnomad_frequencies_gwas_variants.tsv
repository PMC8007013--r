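variant	gene	Global	African	American	Ashkenazi Jewish	East Asian	European	Other
NM_024006.4:c.-4931C>T	VKORC1	0.5758	0.5408	0.542	0.514	0.1007	0.63146	0.619
NM_024006.4:c.-4851C>T	VKORC1							
NM_024006.4:c.-2834C>A	VKORC1	0.0049	0.0001	0.001	0	0	0.00762	0.007
NM_024006.4:c.-1639G>A	VKORC1	0.326	0.1009	0.444	0.476	0.8996	0.37236	0.369
NM_024006.4:c.174-136C>T	VKORC1	0.3261	0.1009	0.443	0.476	0.8995	0.37264	0.37
NM_024006.4:c.283+124G>C	VKORC1	0.4163	0.2564	0.442		0.8849		
NM_024006.4:c.283+837T>C	VKORC1	0.6431	0.7907	0.546	0.517	0.1017	0.62682	0.628
NM_014699.3:c.*2082G>C	VKORC1	0.0049	0.0001	0.001	0	0	0.00763	0.007
NM_014699.3:c.*2737G>T	VKORC1	0.0048	0.017	0.002	0	0	0.00005	0
NM_000062.2:c.-3537C>G	SERPING1	0.0275	0.0078	0.021	0.017	0	0.03846	0.041
NM_000062.2:c.-2415G>A	SERPING1	0.0939	0.0866	0.059	0.141	0.1113	0.09708	0.087
NM_000062.2:c.-1675G>A	SERPING1	0.0937	0.0862	0.059	0.141	0.1105	0.09697	0.087
NM_000062.2:c.52-696C>T	SERPING1	0.3927	0.4767	0.529	0.452	0.7655	0.31673	0.386
NM_000062.2:c.52-130C>T	SERPING1	0.385	0.448	0.525	0.455	0.7668	0.31739	0.385
NM_000062.2:c.52-130C>T	SERPING1	0.385	0.448	0.525	0.455	0.7668	0.31739	0.385
NM_000062.2:c.550+794C>A	SERPING1	0.3936	0.4761	0.531	0.451	0.7697	0.31779	0.388
NM_000062.2:c.685+88G>A	SERPING1	0.2225	0.1006	0.15	0.262	0.1157	0.28733	0.273
NM_000062.2:c.685+1391C>T	SERPING1	0.0248	0.0059	0.022	0.035	0	0.03499	0.038
NM_000062.2:c.685+659C>T	SERPING1	0.3901	0.4743	0.541	0.455	0.769	0.31084	0.381
NM_000062.2:c.685+659C>T	SERPING1	0.3901	0.4743	0.541	0.455	0.769	0.31084	0.381
NM_000062.2:c.685+1100C>T	SERPING1	0.2253	0.1124	0.147	0.262	0.1208	0.28765	0.274
NM_000062.2:c.685+1550G>T	SERPING1	0.2251	0.1127	0.152	0.264	0.1207	0.28734	0.269
NM_000062.2:c.685+1770C>T	SERPING1	0.2216	0.0992	0.15	0.262	0.1184	0.28696	0.27
NM_000062.2:c.1029+926G>T	SERPING1	0.2279	0.1	0.15	0.264	0.1224	0.29523	0.284
NM_000062.2:c.1029+1443G>C	SERPING1	0.2282	0.1004	0.15	0.269	0.1198	0.29577	0.284
NM_000062.2:c.1029+2110T>C	SERPING1	0.612	0.5191	0.469	0.538	0.2347	0.69271	0.624
NM_000062.2:c.1029+2111G>A	SERPING1	0.227	0.1003	0.15	0.264	0.1183	0.29407	0.283
NM_000062.2:c.1030-2243T>G	SERPING1	0.6129	0.5195	0.47	0.541	0.2387	0.69335	0.626
NM_000062.2:c.1030-1975G>C	SERPING1	0.0113	0.0022	0.008	0.024	0	0.01647	0.008
NM_000062.2:c.1030-1436T>C	SERPING1	0.0045	0.0014	0.001	0.003	0	0.00645	0.004
NM_000062.2:c.1030-20A>G	SERPING1	0.6134	0.5197	0.472	0.541	0.2461	0.69353	0.623
NM_000062.2:c.1438G>A	SERPING1	0.2282	0.1007	0.15	0.269	0.1202	0.29561	0.285
NM_000062.2:c.*1323G>A	SERPING1	0.2283	0.1009	0.151	0.269	0.1175	0.29578	0.285
NM_000062.2:c.*1521G>T	SERPING1	0.1496	0.0855	0.166		0.0942		
NM_000062.2:c.*2614A>T	SERPING1	0.6058	0.4936	0.463	0.538	0.2277	0.69504	0.626
NM_003819.3:c.-5600T>C	PABPC4	0.8127	0.5571	0.918	0.945	0.9909	0.90666	0.891
NM_003819.3:c.-4432G>A	PABPC4	0.0403	0.0093	0.095	0.024	0.3712	0.02506	0.047
NM_003819.3:c.-4428A>G	PABPC4	0.0432	0.0096	0.1	0.024	0.3712	0.02918	0.052
NM_003819.3:c.-3677T>G	PABPC4	0.1792	0.0535	0.122	0.247	0.1111	0.24258	0.219
NM_003819.3:c.-3636G>A	PABPC4	0.0052	0.0027	0.004	0.007	0	0.0068	0.007
NM_003819.3:c.-3198T>C	PABPC4	0.0025	0.001	0.002	0	0	0.00329	0.004
NM_003819.3:c.-2286T>G	PABPC4	0.0136	0.0031	0.014	0.01	0	0.01952	0.015
NM_003819.3:c.-650C>T	PABPC4	0.0079	0.0027	0.002	0	0	0.01172	0.008
NM_003819.3:c.193+796C>G	PABPC4	0.8013	0.509	0.913	0.945	0.9904	0.90714	0.895
NM_003819.3:c.504-254C>A	PABPC4	0.1438	0.0321	0.079	0.2	0.1093	0.19797	0.183
NM_003819.3:c.738+85T>C	PABPC4	0.0573	0.1955	0.012	0.01	0.0013	0.00354	0.014
NM_003819.3:c.877-387C>T	PABPC4	0.113	0.0243	0.065	0.131	0.1086	0.15452	0.146
NM_003819.3:c.972+53A>T	PABPC4	0.0018	0.0065	0	0	0	0	0
NM_003819.3:c.972+704C>G	PABPC4	0.0025	0.001	0.002	0	0	0.00328	0.004
NM_003819.3:c.1333+26C>G	PABPC4	0.0006	0.0001	0	0	0	0.00095	0
NM_003819.3:c.1621-348C>G	PABPC4	0.0003	0.0001	0	0	0	0.00042	0
NM_003819.3:c.*765C>A	PABPC4	0.0403	0.0086	0.096	0.024	0.3656	0.02561	0.049
NM_003819.3:c.*1261C>T	PABPC4	0.0073	0.0256	0	0	0.0006	0.00005	0.003
NM_003819.3:c.*4685A>G	PABPC4	0.7986	0.4999	0.911	0.945	0.991	0.90696	0.894
NM_003819.3:c.*5316C>T	PABPC4	0.007	0.0028	0.008	0	0	0.00955	0.008
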