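variant	gene	location	fraction_matching	splicing	mfe_z	mirna_summary
NM_024006.4:c.-4931C>T	VKORC1	5' UTR	0.431818		2.20025	
NM_024006.4:c.-4851C>T	VKORC1	5' UTR	0.754967		1.06847	
NM_024006.4:c.-2834C>A	VKORC1	5' UTR	0.950943			miRNA gained
NM_024006.4:c.-1639G>A	VKORC1	5' UTR	0.0625	Possible splicing change		
NM_024006.4:c.174-136C>T	VKORC1	Intron	0.020228		0.83549	
NM_024006.4:c.283+124G>C	VKORC1	Intron	0.133333		-1.44871	
NM_024006.4:c.283+837T>C	VKORC1	Intron	0.146727		1.35367	
NM_000062.2:c.-3537C>G	SERPING1	5' UTR	0.009615			miRNA decrease
NM_000062.2:c.-2415G>A	SERPING1	5' UTR	0.033708	Possible splicing change	0.77565	
NM_000062.2:c.-1675G>A	SERPING1	5' UTR	0.426901			miRNA gained
NM_000062.2:c.52-696C>T	SERPING1	Intron	0.068027	Likely splicing change	0.30003	
NM_000062.2:c.52-130C>T	SERPING1	Intron	0.833333			
NM_000062.2:c.52-130C>T	SERPING1	Intron	0.833333		-0.28155	
NM_000062.2:c.550+794C>A	SERPING1	Intron	0.693694		0.71906	
NM_000062.2:c.685+88G>A	SERPING1	Intron	0.769231		-0.75902	
NM_000062.2:c.685+659C>T	SERPING1	Intron	0.581818		-0.47852	miRNA decrease
NM_000062.2:c.685+659C>T	SERPING1	Intron	0.679245		-0.68662	
NM_000062.2:c.685+1100C>T	SERPING1	Intron	0.772313		2.01226	
NM_000062.2:c.685+1391C>T	SERPING1	Intron	0.841912	Likely splicing change		
NM_000062.2:c.685+1550G>T	SERPING1	Intron	0.926641			
NM_000062.2:c.685+1770C>T	SERPING1	Intron	0.793594		0.84106	
NM_000062.2:c.1029+926G>T	SERPING1	Intron	0.015723			miRNA gained
NM_000062.2:c.1029+1443G>C	SERPING1	Intron	0.595745			miRNA gained
NM_000062.2:c.1029+2110T>C	SERPING1	Intron	0.393617	Likely splicing change		
NM_000062.2:c.1029+2111G>A	SERPING1	Intron	0.687117			miRNA gained
NM_000062.2:c.1030-2243T>G	SERPING1	Intron	0.026616		-1.68665	
NM_000062.2:c.1030-1975G>C	SERPING1	Intron	0.02551		1.92651	
NM_000062.2:c.1030-1436T>C	SERPING1	Intron	0.823529			
NM_000062.2:c.1030-20A>G	SERPING1	Intron	0.25		-0.76751	
NM_000062.2:c.1438G>A	SERPING1	Exon	0.399177	Possible splicing change		
NM_000062.2:c.*1323G>A	SERPING1	3' UTR	0.878788			miRNA lost
NM_000062.2:c.*1521G>T	SERPING1	3' UTR	0.65873			
NM_000062.2:c.*2614A>T	SERPING1	3' UTR	0.016129			miRNA gained
NM_003819.3:c.-5600T>C	PABPC4	5' UTR	0.48			miRNA lost
NM_003819.3:c.-4432G>A	PABPC4	5' UTR	0.009317			miRNA gained
NM_003819.3:c.-4428A>G	PABPC4	5' UTR	0.221505			
NM_003819.3:c.-3677T>G	PABPC4	5' UTR	0.021645	Possible splicing change	-0.59763	
NM_003819.3:c.-3636G>A	PABPC4	5' UTR	0.022378		2.31727	
NM_003819.3:c.-3198T>C	PABPC4	5' UTR	0.856079	Possible splicing change		miRNA lost
NM_003819.3:c.-2286T>G	PABPC4	5' UTR	0.210526			
NM_003819.3:c.-650C>T	PABPC4	5' UTR	0.829978			miRNA lost
NM_003819.3:c.193+796C>G	PABPC4	Intron	0.666667			
NM_003819.3:c.504-254C>A	PABPC4	Intron	0.247191		0.26322	
NM_003819.3:c.738+85T>C	PABPC4	Intron	0.333333			miRNA lost
NM_003819.3:c.877-387C>T	PABPC4	Intron	1			miRNA lost
NM_003819.3:c.972+53A>T	PABPC4	Intron	1			
NM_003819.3:c.972+704C>G	PABPC4	Intron	0.5			
NM_003819.3:c.1333+26C>G	PABPC4	Intron	0.3125	Likely splicing change		
NM_003819.3:c.1621-348C>G	PABPC4	Intron	1			
NM_003819.3:c.*765C>A	PABPC4	3' UTR	1		1.96974	
NM_003819.3:c.*1261C>T	PABPC4	3' UTR	0.771242		-0.91257	miRNA decrease
NM_003819.3:c.*4685A>G	PABPC4	3' UTR	0.054945		-3.4524	miRNA decrease
NM_003819.3:c.*5316C>T	PABPC4	3' UTR	0.696181	Possible splicing change		miRNA lost
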