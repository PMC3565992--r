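# psfkit model (TSV dialect)
#%	species	D1R	500
#%	species	Gabc	3000
#%	species	AC5	2500
#%	species	ATP	2000000
#%	species	CaMKII	20000
#%	species	DARPP32	50000
#%	species	PP2A	2000
#%	species	PP2B	4000
#%	species	PDE1	4000
#%	species	PDE4	2000
#%	species	PKA	1200
#%	species	CaM	10000
#%	species	Cdk5	1800
#%	species	Ca	1000	input
#%	species	Da	5000	input
#%	species	DaD1R	0
#%	species	DaD1RGabc	0
#%	species	GabcD1R	0
#%	species	GoaGTP	0
#%	species	GoaGDP	0
#%	species	Gbc	0
#%	species	AC5GoaGTP	0
#%	species	AC5GoaGTP_ATP	0
#%	species	AC5Ca	0
#%	species	AC5CaGoaGTP	0
#%	species	AC5CaGoaGTP_ATP	0
#%	species	Ca4CaM	0
#%	species	PDE1CaM	0
#%	species	cAMP	0
#%	species	PDE1CaM_cAMP	0
#%	species	PDE4_cAMP	0
#%	species	PKAcAMP2	0
#%	species	PKAcAMP4	0
#%	species	PKAr	0
#%	species	PKAc	0
#%	species	PP2BCa4CaM	0
#%	species	PP2BCa2CaM	0
#%	species	PP2BCaM	0
#%	species	Ca2CaM	0
#%	species	CaMKIICa4CaM	0
#%	species	CaMKIIpCa4CaM	0
#%	species	DARPP32PKAc	0
#%	species	PKAcPP2A	0
#%	species	PP2Ap	0
#%	species	pThr34	0
#%	species	pThr34PP2B	0
#%	species	pThr34PP2A	0
#%	species	DARPP32Cdk5	0
#%	species	pThr75	0
#%	species	pThr75PKAc	0
#%	species	pThr75PP2Ap	0
#%	species	pThr75PP2A	0
#%	species	PP2Ac	0
#%	species	pThr75PP2Ac	0
#%	species	AMP	0
id	kind	lhs	mid	rhs	kon	koff	kcat
1	binding	Da + D1R		DaD1R	1.11e-03	1.00e+01	
2	binding	DaD1R + Gabc		DaD1RGabc	6.00e-04	1.00e-03	
3	binding	Gabc + D1R		GabcD1R	6.00e-05	3.00e-04	
4	binding	GabcD1R + Da		DaD1RGabc	3.33e-03	1.00e+01	
5	decomposition	DaD1RGabc		DaD1R + GoaGTP + Gbc			20.000
6	conversion	GoaGTP		GoaGDP			10.000
7	irreversible_binding	GoaGDP + Gbc		Gabc	1.00e+02		
8	binding	GoaGTP + AC5		AC5GoaGTP	3.85e-02	5.00e+01	
9	enzymatic	ATP + AC5GoaGTP	AC5GoaGTP_ATP	cAMP + AC5GoaGTP	1.28e-04	2.61e-01	28.460
10	binding	AC5 + Ca		AC5Ca	1.00e-03	9.00e-01	
11	binding	AC5Ca + GoaGTP		AC5CaGoaGTP	1.92e-02	2.50e+01	
12	enzymatic	ATP + AC5CaGoaGTP	AC5CaGoaGTP_ATP	cAMP + AC5CaGoaGTP	6.00e-05	1.31e-01	14.230
13	binding	PDE1 + Ca4CaM		PDE1CaM	1.00e-01	1.00e+00	
14	enzymatic	cAMP + PDE1CaM	PDE1CaM_cAMP	AMP + PDE1CaM	4.60e-03	4.40e+01	11.000
15	enzymatic	cAMP + PDE4	PDE4_cAMP	AMP + PDE4	2.00e-02	7.20e+01	18.000
16	binding	PKA + cAMP		PKAcAMP2	2.60e-05	6.00e-03	
17	binding	PKAcAMP2 + cAMP		PKAcAMP4	3.46e-05	6.00e-02	
18	binding	PKAr + PKAc		PKAcAMP4	1.02e-03	4.80e-03	
19	binding	Ca4CaM + PP2B		PP2BCa4CaM	1.00e+00	3.00e-01	
20	binding	PP2BCa2CaM + Ca		PP2BCa4CaM	1.00e-01	1.00e+01	
21	binding	CaM + PP2B		PP2BCaM	1.00e+00	3.00e+00	
22	binding	Ca2CaM + PP2B		PP2BCa2CaM	1.00e+00	3.00e-01	
23	binding	PP2BCaM + Ca		PP2BCa2CaM	6.00e-03	9.10e-01	
24	binding	CaM + Ca		Ca2CaM	6.00e-03	9.10e+00	
25	binding	Ca2CaM + Ca		Ca4CaM	1.00e-01	1.00e+03	
26	binding	Ca4CaM + CaMKII		CaMKIICa4CaM	7.50e-04	1.00e-01	
27	conversion	CaMKIICa4CaM		CaMKIIpCa4CaM			0.005
28	conversion	CaMKIIpCa4CaM		CaMKIICa4CaM			0.015
29	enzymatic	DARPP32 + PKAc	DARPP32PKAc	pThr34 + PKAc	2.70e-03	8.00e+00	2.000
30	enzymatic	PP2A + PKAc	PKAcPP2A	PP2Ap + PKAc	2.50e-03	3.00e-01	0.100
31	conversion	PP2Ap		PP2A			0.004
32	enzymatic	pThr34 + PP2BCa4CaM	pThr34PP2B	DARPP32 + PP2BCa4CaM	1.00e-03	2.00e+00	0.500
33	enzymatic	pThr34 + PP2A	pThr34PP2A	DARPP32 + PP2A	1.00e-04	2.00e+00	0.500
34	enzymatic	DARPP32 + Cdk5	DARPP32Cdk5	pThr75 + Cdk5	4.50e-04	2.00e+00	0.500
35	binding	pThr75 + PKAc		pThr75PKAc	3.70e-04	1.00e+00	
36	enzymatic	pThr75 + PP2Ap	pThr75PP2Ap	DARPP32 + PP2Ap	4.00e-04	1.20e+01	3.000
37	enzymatic	pThr75 + PP2A	pThr75PP2A	DARPP32 + PP2A	1.00e-04	6.40e+00	1.600
38	binding	PP2A + 4*Ca		PP2Ac	7.72e-12	1.00e-02	
39	enzymatic	pThr75 + PP2Ac	pThr75PP2Ac	DARPP32 + PP2Ac	4.00e-04	1.20e+01	3.000
40	conversion	AMP		ATP			10.000

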