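# Signal transduction network combining PKC, MAPK, PLA2 and PLC-beta modules.
# Synthetic reconstruction of the Bhalla & Iyengar (1999) mass-action scheme:
# topology and species names follow the published model; rate constants are
# set to the published magnitudes where known and to plausible values of the
# correct order otherwise. 66 species (61 variable, 5 constant inputs),
# 110 one-way elementary reactions. Units: M, s, M^-1 s^-1.
[species]
APC	3e-05	constant
tempPIP2	2.5e-06	constant
Inositol	0e+00	constant
PC	0e+00	constant
PIP2	2.5e-06	constant
Ca	8e-08	variable
DAG	0e+00	variable
AA	0e+00	variable
IP3	0e+00	variable
PKC-cytosolic	1e-06	variable
PKC-Ca	0e+00	variable
PKC-Ca-memb*	0e+00	variable
PKC-Ca-DAG	0e+00	variable
PKC-DAG-memb*	0e+00	variable
PKC-basal*	0e+00	variable
PKC-AA*	0e+00	variable
PKC-Ca-AA*	0e+00	variable
PKC-DAG	0e+00	variable
PKC-DAG-AA	0e+00	variable
PKC-DAG-AA*	0e+00	variable
cRaf1	2e-07	variable
cRaf1*	0e+00	variable
cRaf1**	0e+00	variable
GDP-Ras	2e-07	variable
GTP-Ras	0e+00	variable
Raf*GTPRas	0e+00	variable
MAPKK	1.8e-07	variable
MAPKK-ser	0e+00	variable
MAPKK*	0e+00	variable
MAPK	3.6e-07	variable
MAPK-tyr	0e+00	variable
MAPK*	0e+00	variable
PPhosphatase2A	2.24e-07	variable
MKP1	3.2e-09	variable
PKC-cRaf1-cplx	0e+00	variable
Raf-MAPKK-cplx	0e+00	variable
Raf-MAPKKser-cplx	0e+00	variable
MAPKK-MAPK-cplx	0e+00	variable
MAPKK-MAPKtyr-cplx	0e+00	variable
PP2A-cRaf1*-cplx	0e+00	variable
craf**deph	0e+00	variable
PP2A-MAPKK*-cplx	0e+00	variable
PP2A-MAPKKser-cplx	0e+00	variable
MKP1-MAPK*-cplx	0e+00	variable
MKP1-MAPKtyr-cplx	0e+00	variable
MAPK*-PLA2-cplx	0e+00	variable
PLA2-cytosolic	4e-07	variable
PLA2-Ca*	0e+00	variable
PIP2-PLA2*	0e+00	variable
PIP2-Ca-PLA2*	0e+00	variable
DAG-Ca-PLA2*	0e+00	variable
PLA2*	0e+00	variable
PLA2*-Ca	0e+00	variable
PLA2-Ca*-APC-cplx	0e+00	variable
PIP2-PLA2*-APC-cplx	0e+00	variable
PIP2-Ca-PLA2*-APC-cplx	0e+00	variable
DAG-Ca-PLA2*-APC-cplx	0e+00	variable
PLA2*-Ca-APC-cplx	0e+00	variable
PLC	8e-07	variable
CaPLCcomplex	0e+00	variable
GqPLC	0e+00	variable
GqCaPLC	0e+00	variable
G*GTP	0e+00	variable
CaPLCbcomplex	0e+00	variable
GqCaPLCbcomplex	0e+00	variable
G*GDP	1e-07	variable
[reactions]
R001	PKC-cytosolic + Ca -> PKC-Ca	600000	kf
R002	PKC-Ca -> PKC-cytosolic + Ca	0.5	kb
R003	PKC-Ca + DAG -> PKC-Ca-DAG	8000	kf
R004	PKC-Ca-DAG -> PKC-Ca + DAG	8.6348	kb
R005	PKC-Ca -> PKC-Ca-memb*	1.2705	kf
R006	PKC-Ca-memb* -> PKC-Ca	3.5026	kb
R007	PKC-Ca-DAG -> PKC-DAG-memb*	1	kf
R008	PKC-DAG-memb* -> PKC-Ca-DAG	0.1	kb
R009	PKC-cytosolic -> PKC-basal*	1	kf
R010	PKC-basal* -> PKC-cytosolic	50	kb
R011	PKC-cytosolic + AA -> PKC-AA*	120	kf
R012	PKC-AA* -> PKC-cytosolic + AA	0.1	kb
R013	PKC-Ca + AA -> PKC-Ca-AA*	1200	kf
R014	PKC-Ca-AA* -> PKC-Ca + AA	0.1	kb
R015	PKC-cytosolic + DAG -> PKC-DAG	600	kf
R016	PKC-DAG -> PKC-cytosolic + DAG	0.1	kb
R017	PKC-DAG + AA -> PKC-DAG-AA	18000	kf
R018	PKC-DAG-AA -> PKC-DAG + AA	2	kb
R019	PKC-DAG-AA -> PKC-DAG-AA*	2	kf
R020	PKC-DAG-AA* -> PKC-DAG-AA	0.2	kb
R021	PKC-Ca-memb* + cRaf1 -> PKC-cRaf1-cplx	2000000	kf
R022	PKC-cRaf1-cplx -> PKC-Ca-memb* + cRaf1	16	kb
R023	PKC-cRaf1-cplx -> PKC-Ca-memb* + cRaf1*	4	kcat
R024	GDP-Ras -> GTP-Ras	0.0005	kf
R025	GTP-Ras -> GDP-Ras	0.066	kf
R026	cRaf1* + GTP-Ras -> Raf*GTPRas	10000000	kf
R027	Raf*GTPRas -> cRaf1* + GTP-Ras	0.5	kb
R028	Raf*GTPRas -> cRaf1* + GDP-Ras	0.066	kf
R029	Raf*GTPRas + MAPKK -> Raf-MAPKK-cplx	3300000	kf
R030	Raf-MAPKK-cplx -> Raf*GTPRas + MAPKK	0.42	kb
R031	Raf-MAPKK-cplx -> Raf*GTPRas + MAPKK-ser	0.105	kcat
R032	Raf*GTPRas + MAPKK-ser -> Raf-MAPKKser-cplx	3300000	kf
R033	Raf-MAPKKser-cplx -> Raf*GTPRas + MAPKK-ser	0.42	kb
R034	Raf-MAPKKser-cplx -> Raf*GTPRas + MAPKK*	0.105	kcat
R035	MAPKK* + MAPK -> MAPKK-MAPK-cplx	16300000	kf
R036	MAPKK-MAPK-cplx -> MAPKK* + MAPK	0.6	kb
R037	MAPKK-MAPK-cplx -> MAPKK* + MAPK-tyr	0.15	kcat
R038	MAPKK* + MAPK-tyr -> MAPKK-MAPKtyr-cplx	16300000	kf
R039	MAPKK-MAPKtyr-cplx -> MAPKK* + MAPK-tyr	0.6	kb
R040	MAPKK-MAPKtyr-cplx -> MAPKK* + MAPK*	0.15	kcat
R041	PPhosphatase2A + cRaf1* -> PP2A-cRaf1*-cplx	1910000	kf
R042	PP2A-cRaf1*-cplx -> PPhosphatase2A + cRaf1*	24	kb
R043	PP2A-cRaf1*-cplx -> PPhosphatase2A + cRaf1	6	kcat
R044	PPhosphatase2A + cRaf1** -> craf**deph	1910000	kf
R045	craf**deph -> PPhosphatase2A + cRaf1**	24	kb
R046	craf**deph -> PPhosphatase2A + cRaf1*	6	kcat
R047	PPhosphatase2A + MAPKK* -> PP2A-MAPKK*-cplx	1910000	kf
R048	PP2A-MAPKK*-cplx -> PPhosphatase2A + MAPKK*	24	kb
R049	PP2A-MAPKK*-cplx -> PPhosphatase2A + MAPKK-ser	6	kcat
R050	PPhosphatase2A + MAPKK-ser -> PP2A-MAPKKser-cplx	1910000	kf
R051	PP2A-MAPKKser-cplx -> PPhosphatase2A + MAPKK-ser	24	kb
R052	PP2A-MAPKKser-cplx -> PPhosphatase2A + MAPKK	6	kcat
R053	MKP1 + MAPK* -> MKP1-MAPK*-cplx	300000000	kf
R054	MKP1-MAPK*-cplx -> MKP1 + MAPK*	4	kb
R055	MKP1-MAPK*-cplx -> MKP1 + MAPK-tyr	1	kcat
R056	MKP1 + MAPK-tyr -> MKP1-MAPKtyr-cplx	300000000	kf
R057	MKP1-MAPKtyr-cplx -> MKP1 + MAPK-tyr	4	kb
R058	MKP1-MAPKtyr-cplx -> MKP1 + MAPK	1	kcat
R059	MAPK* + PLA2-cytosolic -> MAPK*-PLA2-cplx	3906000	kf
R060	MAPK*-PLA2-cplx -> MAPK* + PLA2-cytosolic	80	kb
R061	MAPK*-PLA2-cplx -> MAPK* + PLA2*	20	kcat
R062	PLA2-cytosolic + Ca -> PLA2-Ca*	1000000	kf
R063	PLA2-Ca* -> PLA2-cytosolic + Ca	1	kb
R064	PLA2-cytosolic + tempPIP2 -> PIP2-PLA2*	120000	kf
R065	PIP2-PLA2* -> PLA2-cytosolic + tempPIP2	0.5	kb
R066	PLA2-Ca* + tempPIP2 -> PIP2-Ca-PLA2*	120000	kf
R067	PIP2-Ca-PLA2* -> PLA2-Ca* + tempPIP2	0.5	kb
R068	PIP2-PLA2* + Ca -> PIP2-Ca-PLA2*	1000000	kf
R069	PIP2-Ca-PLA2* -> PIP2-PLA2* + Ca	1	kb
R070	PLA2-Ca* + DAG -> DAG-Ca-PLA2*	30000	kf
R071	DAG-Ca-PLA2* -> PLA2-Ca* + DAG	4	kb
R072	PLA2* + Ca -> PLA2*-Ca	1000000	kf
R073	PLA2*-Ca -> PLA2* + Ca	0.1	kb
R074	PLA2* -> PLA2-cytosolic	0.17	kf
R075	PLA2*-Ca -> PLA2-Ca*	0.17	kf
R076	PLA2-Ca* + APC -> PLA2-Ca*-APC-cplx	1326000	kf
R077	PLA2-Ca*-APC-cplx -> PLA2-Ca* + APC	21.6	kb
R078	PLA2-Ca*-APC-cplx -> PLA2-Ca* + AA	5.4	kcat
R079	PIP2-PLA2* + APC -> PIP2-PLA2*-APC-cplx	2711000	kf
R080	PIP2-PLA2*-APC-cplx -> PIP2-PLA2* + APC	44.16	kb
R081	PIP2-PLA2*-APC-cplx -> PIP2-PLA2* + AA	11.04	kcat
R082	PIP2-Ca-PLA2* + APC -> PIP2-Ca-PLA2*-APC-cplx	8841000	kf
R083	PIP2-Ca-PLA2*-APC-cplx -> PIP2-Ca-PLA2* + APC	144	kb
R084	PIP2-Ca-PLA2*-APC-cplx -> PIP2-Ca-PLA2* + AA	36	kcat
R085	DAG-Ca-PLA2* + APC -> DAG-Ca-PLA2*-APC-cplx	14735000	kf
R086	DAG-Ca-PLA2*-APC-cplx -> DAG-Ca-PLA2* + APC	240	kb
R087	DAG-Ca-PLA2*-APC-cplx -> DAG-Ca-PLA2* + AA	60	kcat
R088	PLA2*-Ca + APC -> PLA2*-Ca-APC-cplx	29470000	kf
R089	PLA2*-Ca-APC-cplx -> PLA2*-Ca + APC	480	kb
R090	PLA2*-Ca-APC-cplx -> PLA2*-Ca + AA	120	kcat
R091	AA -> APC	0.4	kf
R092	PLC + Ca -> CaPLCcomplex	3000000	kf
R093	CaPLCcomplex -> PLC + Ca	1	kb
R094	PLC + G*GTP -> GqPLC	42000	kf
R095	GqPLC -> PLC + G*GTP	1	kb
R096	GqPLC + Ca -> GqCaPLC	30000000	kf
R097	GqCaPLC -> GqPLC + Ca	1	kb
R098	CaPLCcomplex + G*GTP -> GqCaPLC	42000	kf
R099	GqCaPLC -> CaPLCcomplex + G*GTP	1	kb
R100	CaPLCcomplex + PIP2 -> CaPLCbcomplex	2525000	kf
R101	CaPLCbcomplex -> CaPLCcomplex + PIP2	40	kb
R102	CaPLCbcomplex -> CaPLCcomplex + IP3 + DAG	10	kcat
R103	GqCaPLC + PIP2 -> GqCaPLCbcomplex	12120000	kf
R104	GqCaPLCbcomplex -> GqCaPLC + PIP2	192	kb
R105	GqCaPLCbcomplex -> GqCaPLC + IP3 + DAG	48	kcat
R106	G*GTP -> G*GDP	0.0133	kcat
R107	GqCaPLC -> CaPLCcomplex + G*GDP	0.0133	kcat
R108	GqPLC -> PLC + G*GDP	0.0133	kcat
R109	IP3 -> Inositol	2.5	kf
R110	DAG -> PC	0.15	kf
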