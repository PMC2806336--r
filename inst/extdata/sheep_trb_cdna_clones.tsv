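clone_id	tissue	breed	v_aa	ndn_aa	j_aa	accession	d_gene	j_gene	c_gene	cdr3_len_aa
pSTMos.01	young_thymus	Moscia_Leccese	ASSQ	A(GT)VI	SYEQYFGPGTKLTVV	FM993913	TRBD1	TRBJ2.7	TRBC2	14
pSTMos.02	young_thymus	Moscia_Leccese	ASSPT	NIAY	SYEQYFGPGTKLTVV	FM993914	none	TRBJ2.7	TRBC2	14
pSTMos.03	young_thymus	Moscia_Leccese	ASSQ	SD(G)	EQYFGPGTKLTVV	FM993915	TRBD3	TRBJ2.7	TRBC3	10
pSTMos.04	young_thymus	Moscia_Leccese	ASSP	PP(GQ)V	NTEVFFGKGTRLTVV	FM993916	TRBD1	TRBJ1.1	TRBC1	14
pSTMos.05	young_thymus	Moscia_Leccese	ASSQG	R(D)L	SNNPLYFGGGTRLLVL	FM993917	TRBD1	TRBJ2.3	TRBC3	14
pSTMos.06	young_thymus	Moscia_Leccese	ASSQG	P	NTDPLYFGAGSKLTVL	FM993918	none	TRBJ2.2	TRBC2	12
pSTMos.07	young_thymus	Moscia_Leccese	ASSR	VGTME(GQ)I	YNSOLQFGIGTRLTVT	FM993919	TRBD1	TRBJ1.6	TRBC1	18
pSTMos.08	young_thymus	Moscia_Leccese	ASSPT	E(GLWGG)R	YEQYFGPGTKLTVV	FM993920	TRBD2	TRBJ2.7	TRBC3	16
pSTMos.09	young_thymus	Moscia_Leccese	ASSQE	AR(LG)AR	YFGAGTRLSVL	FM993921	TRBD3	TRBJ3.3	TRBC3	12
pSTMos.11	young_thymus	Moscia_Leccese	ASSR	TALRP(LGE)HAL	YGELHFGPGTRLTVL	FM993922	TRBD2	TRBJ2.1	TRBC2	20
pSTMos.12	young_thymus	Moscia_Leccese	ASSPT	PT	YDERHFGPGTRLTVL	FM993923	none	TRBJ3.1	TRBC3	12
pSTMos.13	young_thymus	Moscia_Leccese	ASSR	P(WGQG)D	GELHFGPGTRLTVL	FM993924	TRBD3	TRBJ2.1	TRBC2	14
pSTMos.14	young_thymus	Moscia_Leccese	ASS	G	SNNPLYFGGGTRLLVL	FM993925	none	TRBJ2.3	TRBC2	10
pSTMos.17	young_thymus	Moscia_Leccese	ASSQD	M(G)ASA	AQLYFGAGSKLTVL	FM993926	TRBD3	TRBJ3.2	TRBC3	14
pSTMos.18	young_thymus	Moscia_Leccese	ASSQE	(GA)DH	NPLYFGGGTRLLVL	FM993927	TRBD3	TRBJ2.3	TRBC3	13
pSTMos.19	young_thymus	Moscia_Leccese	ASSQ	W	SNQAQHFGHGTRLAVL	FM993928	none	TRBJ1.5	TRBC1	11
pSTMos.20	young_thymus	Moscia_Leccese	ASSPT	LR(G)IIPT	YEQYFGPGTKLTVV	FM993929	TRBD1	TRBJ2.7	TRBC3	16
pSTMos.21	young_thymus	Moscia_Leccese	ASS	RSR(WG)QD	SERYFGAGTRLTVT	FM993930	TRBD3	TRBJ3.5	TRBC3	14
pSTMos.22	young_thymus	Moscia_Leccese	ASSR	(WG)QD	SERYFGAGTRLTVT	FM993931	TRBD3	TRBJ3.5	TRBC3	12
pSTMos.23	young_thymus	Moscia_Leccese	ASSQ	APYG(TF)	SETQYFGPGTRLLVL	FM993932	TRBD2	TRBJ3.4	TRBC3	15
pSTMos.25	young_thymus	Moscia_Leccese	ASSPT	R(Q)GG	DPLYFGAGSKLTVL	FM993933	TRBD1	TRBJ2.2	TRBC3	13
pSSAR.01	blood	Sarda_Ionica	ASSQ	SRR(D)VS	QTQYFGPGTRLLVL	FM993934	TRBD1	TRBJ2.5	TRBC2	14
pSSAR.02	blood	Sarda_Ionica	ASSQG	HR(TA)K	NERLYFGNGTKLSVL	FM993935	TRBD1	TRBJ1.4	TRBC1	15
pSSAR.04	blood	Sarda_Ionica	ASSQ	(AGGW)AL	SETQYFGPGTRLLVL	FM993936	TRBD3	TRBJ3.4	TRBC3	15
pSSAR.05	blood	Sarda_Ionica	ASSK	LG(R)DILN	EQYFGPGTKLTVV	FM993937	TRBD1	TRBJ2.7	TRBC3	14
pSSAR.07	blood	Sarda_Ionica	ASSQD	S(GTA)D	ERLYFGNGTKLSVL	FM993938	TRBD1	TRBJ1.4	TRBC1	14
pSSAR.08	blood	Sarda_Ionica	ASS	(LG)	NERLYFGNGTKLSVL	FM993939	TRBD3	TRBJ1.4	TRBC1	10
pSSAR.10	blood	Sarda_Ionica	ASSL	DI(R)PN	GELHFGPGTRLTVL	FM993940	TRBD2	TRBJ2.1	TRBC3	13
pSSAR.11	blood	Sarda_Ionica	ASSP	K(RD)GY	NPLYFGGGTRLLVL	FM993941	TRBD1	TRBJ2.3	TRBC2	13
pSSAR.16	blood	Sarda_Ionica	ASSQE	Q(Q)SRF	NNPLYFGGGTRLLVL	FM993942	TRBD1	TRBJ2.3	TRBC1	15
pSSAR.17	blood	Sarda_Ionica	ASSQ	SRRD	SNQAQHFGHGTRLAIL	FM993943	none	TRBJ1.5	TRBC1	14
pSSAR.19	blood	Sarda_Ionica	ASSP	S(DFG)IG	NNPLYFGGGTRLLVL	FM993944	TRBD2	TRBJ2.3	TRBC2	15
pSSAR.23	blood	Sarda_Ionica	ASS	LSTVD	SQSTQYFGAGTRLSVL	FM993945	none	TRBJ3.3	TRBC3	14
pSSAR.24	blood	Sarda_Ionica	ASSQD	RKQGG	NSPLQFGIGTRLTVT	FM993946	none	TRBJ1.6	TRBC1	15
pSSAR.25	blood	Sarda_Ionica	ASS	FFST(G)E	ETQYFGPGTRLLVL	FM993947	TRBD3	TRBJ3.4	TRBC3	13
pSSAR.28	blood	Sarda_Ionica	ASSQ	(GQ)DRI	NPOLYFGGGTRLLVL	FM993948	TRBD1	TRBJ2.3	TRBC2	14
pSSAR.31	blood	Sarda_Ionica	ASSP	DP(DSG)A	AQLYFGAGSKLTVL	FM993949	TRBD1	TRBJ3.2	TRBC3	14
pSSAR.32	blood	Sarda_Ionica	ASSQD	IS(QR)A	TDPLYFGAGSKLTVL	FM993950	TRBD1	TRBJ2.2	TRBC3	15
pSMA.09	spleen	Gentile_di_Puglia	ASSP	(LWGG)D	NPLYFGGGTRLLVL	FM993951	TRBD2	TRBJ2.3	TRBC2	13
pSMA.10	spleen	Gentile_di_Puglia	ASSQD	(AG)F	NPLYFGGGTRLLVL	FM993952	TRBD3	TRBJ2.3	TRBC2	12
pSMA.41	spleen	Gentile_di_Puglia	ASSQ	KR(TAG)	ERHFGPGTRLTVL	FM993953	TRBD1	TRBJ3.1	TRBC3	12
pSMA.42	spleen	Gentile_di_Puglia	ASS	L(GQRG)G	YEQYFGPGTKLTVV	FM993954	TRBD1	TRBJ2.7	TRBC2	13
pSMA.46	spleen	Gentile_di_Puglia	ASSQD	I	ETQYFGPGTRLLVL	FM993955	none	TRBJ3.4	TRBC2	10
pSMA.48	spleen	Gentile_di_Puglia	ASSQE	LT	YEQYFGPGTKLTVV	FM993956	none	TRBJ2.7	TRBC3	11
pSMA.55	spleen	Gentile_di_Puglia	ASSR	(DL)C	NNPLYFGGGTRLLVL	FM993957	TRBD2	TRBJ2.3	TRBC3	12
pSMA.59	spleen	Gentile_di_Puglia	ASSS	V(S)D	GELHFGPGTRLTVL	FM993958	TRBD1	TRBJ2.1	TRBC2	11
pSMA.60	spleen	Gentile_di_Puglia	ASSP	AV(G)SD	NPLYFGGGTRLLVL	FM993959	TRBD1	TRBJ2.3	TRBC3	13
pSMA.62	spleen	Gentile_di_Puglia	ASSP	Q(TAG)E	DPLYFGAGSKLTVL	FM993960	TRBD1	TRBJ2.2	TRBC2	13
pSMA.65	spleen	Gentile_di_Puglia	ASSK	GR(TAG)P	SNNPLYFGGGTRLLVL	FM993961	TRBD1	TRBJ2.3	TRBC3	16
pSMA.66	spleen	Gentile_di_Puglia	ASSS	DR(GW)S	QTQYFGPGTRLLVL	FM993962	TRBD3	TRBJ2.5	TRBC2	13
pSMA.67	spleen	Gentile_di_Puglia	ASSK	TDF	YEQYFGPGTKLTVV	FM993963	none	TRBJ2.7	TRBC2	11
pSMA.68	spleen	Gentile_di_Puglia	ASS	W(T)LNA	AQLYFGAGSKLTVL	FM993964	TRBD1	TRBJ3.2	TRBC2	12
pSMA.70	spleen	Gentile_di_Puglia	ASSR	E(GTG)L	YEQYFGPGTKLTVV	FM993965	TRBD1	TRBJ2.7	TRBC3	13
pSMA.71	spleen	Gentile_di_Puglia	ASSP	(GP)T	NTEVFFGKGTRLTVV	FM993966	TRBD1	TRBJ1.1	TRBC1	12
pSMA.73	spleen	Gentile_di_Puglia	ASSP	FL(DS)V	DERHFGPGTRLTVL	FM993967	TRBD1	TRBJ3.1	TRBC3	13
pSMA.74	spleen	Gentile_di_Puglia	ASS	R(H)QNI	TDTQYFGPGTRLSVL	FM993968	TRBD1	TRBJ2.4	TRBC2	13
pSMA.76	spleen	Gentile_di_Puglia	ASSP	(S)	SNNPLYFGGGTRLLVL	FM993969	TRBD3	TRBJ2.3	TRBC2	11
pSTA.01	adult_thymus	Gentile_di_Puglia	ASSR	Y(SE)GD	EYHFGPGTKLTVV	FM993970	TRBD1	TRBJ1.2	TRBC3	12
pSTA.02	adult_thymus	Gentile_di_Puglia	ASSQD	LV(GTA)R	YEYHFGPGTKLTVV	FM993971	TRBD1	TRBJ1.2	TRBC3	15
pSTA.03	adult_thymus	Gentile_di_Puglia	ASS	FFST(G)E	ETQYFGPGTRLLVL	FM993972	TRBD3	TRBJ3.4	TRBC3	13
pSTA.04	adult_thymus	Gentile_di_Puglia	ASS	DS(W)DVQS	TQYFGPGTRLLVL	FM993973	TRBD3	TRBJ3.4	TRBC3	13
pSTA.06	adult_thymus	Gentile_di_Puglia	ASSQD	(R)D	YEYHFGPGTKLTVV	FM993974	TRBD1	TRBJ1.2	TRBC3	11
pSTA.08	adult_thymus	Gentile_di_Puglia	ASSP	S(R)D	TEVFFGKGTRLTVV	FM993975	TRBD1	TRBJ1.1	TRBC3	11
pSTA.09	adult_thymus	Gentile_di_Puglia	ASS	(LR)	ETQYFGPGTRLLVL	FM993976	TRBD2	TRBJ3.4	TRBC3	9
pSTA.11	adult_thymus	Gentile_di_Puglia	ASSP	(GQR)PP	DTQYFGPGTRLSVL	FM993977	TRBD1	TRBJ2.4	TRBC2	13
pSTA.12	adult_thymus	Gentile_di_Puglia	ASS	LS(GTRG)D	TQTQYFGPGTRLLVL	FM993978	TRBD1	TRBJ2.5	TRBC2	15
pSTA.13	adult_thymus	Gentile_di_Puglia	ASSR	K(RG)H	SETQYFGPGTRLLVL	FM993979	TRBD1	TRBJ3.4	TRBC3	13
pSTA.15	adult_thymus	Gentile_di_Puglia	ASS	IEKA	NPLYFGGGTRLLVL	FM993980	none	TRBJ2.3	TRBC2	11
pSTA.24	adult_thymus	Gentile_di_Puglia	ASSK	DL(AGG)VS	SETQYFGPGTRLLVL	FM993981	TRBD3	TRBJ3.4	TRBC2	16
pSTA.25	adult_thymus	Gentile_di_Puglia	ASSL	ER(QR)	DERHFGPGTRLTVL	FM993982	TRBD1	TRBJ3.1	TRBC3	12
pSTA.26	adult_thymus	Gentile_di_Puglia	ASSP	R(S)DK	GELHFGPGTRLTVL	FM993983	TRBD1	TRBJ2.1	TRBC1	12
pSTA.29	adult_thymus	Gentile_di_Puglia	ASSP	RQ(T)GPFG	EYHFGPGTKLTVV	FM993984	TRBD1	TRBJ1.2	TRBC1	14
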