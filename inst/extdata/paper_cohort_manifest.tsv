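# Synthetic planted-truth cohort manifest (117 families).
# One row = one family = one cohort unit.
#expect	total=117
#expect	mtdna=23
#expect	nuclear=57
#expect	none=37
#expect	strategyA=42
#expect	strategyB=75
family_id	consanguineous	n_affected	group	mdc_score	categories	genes	mitocarta	variant_info	mt_signature	affected_sex	parents_available	subclinical_parent
MT001	no	2	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT002	no	2	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT003	no	1	1	7	mt_point	.	.	3243:A:G:0.24	.	.	yes	.
MT004	no	1	1	7	mt_point	.	.	3243:A:G:0.41	.	.	yes	.
MT005	no	1	1	7	mt_point	.	.	3243:A:G:0.25	.	.	yes	.
MT006	no	1	1	7	mt_point	.	.	3243:A:G:0.26	.	.	yes	.
MT007	no	1	1	7	mt_point	.	.	3243:A:G:0.10	.	.	yes	.
MT008	no	1	1	7	mt_point	.	.	3243:A:G:0.07	.	.	yes	.
MT009	no	1	1	7	mt_point	.	.	3243:A:G:0.40	.	.	yes	.
MT010	no	1	1	8	mt_point	.	.	13513:G:A:0.72	.	.	yes	.
MT011	no	1	1	7	mt_point	.	.	11778:G:A:0.80	.	.	yes	.
MT012	no	1	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT013	no	1	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT014	no	1	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT015	no	1	1	7	mt_point	.	.	11778:G:A:1.0	.	.	yes	.
MT016	no	1	1	7	mt_point	.	.	14484:T:C:1.0	.	.	yes	.
MT017	no	1	1	7	mt_point	.	.	14484:T:C:1.0	.	.	yes	.
MT018	no	1	1	7	mt_single_deletion	.	.	del:7462:15747	.	.	yes	.
MT019	no	1	1	7	mt_single_deletion	.	.	del:9514:15792	.	.	yes	.
MT020	no	1	1	8	mt_single_deletion	.	.	del:8482:13460	.	.	yes	.
MT021	no	1	1	8	mt_single_deletion	.	.	del:8482:13460	.	.	yes	.
MT022	no	1	1	8	mt_single_deletion	.	.	del:8482:13460	.	.	yes	.
MT023	no	1	1	8	mt_single_deletion	.	.	del:8482:13460	.	.	yes	.
WA01	no	3	1	8	nuclear_AR_comphet	AARS2	yes	.	.	.	yes	.
WA02	yes	2	1	8	nuclear_AR_hom;nuclear_AR_hom;nuclear_AR_hom	SERAC1;ACY1;ANTXR2	yes;no;no	.	.	.	yes	.
WA03	yes	2	1	6	nuclear_AR_hom	SPG7	yes	.	.	.	yes	.
WA04	yes	2	1	8	nuclear_AR_hom	FBXL4	yes	.	.	.	yes	.
WA05	no	3	1	7	nuclear_AR_comphet	MTFMT	yes	.	.	.	yes	.
WA06	yes	1	1	5	nuclear_AR_hom	NDUFAF4	yes	.	.	.	yes	.
WA07	yes	2	1	5	nuclear_AR_hom	QRSL1	yes	.	.	.	yes	.
WA08	yes	1	1	8	nuclear_AR_hom	SLC25A46	yes	.	.	.	yes	.
WA09	yes	1	1	8	nuclear_AR_comphet	RRM2B	no	.	depletion	.	yes	.
WA10	no	2	1	5	nuclear_AR_comphet	COQ7	yes	.	.	.	yes	.
WA11	yes	1	1	5	nuclear_AR_hom	NDUFAF5	yes	.	.	.	yes	.
WA12	yes	1	1	5	nuclear_AR_hom	TMEM126A	yes	.	.	.	yes	.
WA13	yes	3	1	6	nuclear_AR_hom	PYCR2	yes	.	.	.	yes	.
WA14	yes	3	1	7	nuclear_AR_hom	SLC19A3	no	.	.	.	yes	.
WA15	yes	2	1	7	nuclear_AR_hom	SLC19A3	no	.	.	.	yes	.
WA16	no	2	1	6	nuclear_XLR	SLC16A2	no	.	.	M;M	yes	.
WA17	yes	1	1	7	nuclear_AR_hom	IER3IP1	no	.	.	.	yes	.
WB01	no	1	1	5	nuclear_AR_comphet	POLG1	yes	.	multiple_deletions	.	yes	.
WB02	no	1	1	5	nuclear_AR_hom	POLG1	yes	.	multiple_deletions	.	yes	.
WB03	no	1	1	6	nuclear_AR_hom	NDUFS7	yes	.	.	.	yes	.
WB04	no	1	1	6	nuclear_AR_comphet	MTO1	yes	.	.	.	yes	.
WB05	no	1	1	6	nuclear_AR_comphet	SPG7	yes	.	.	.	yes	.
WB06	no	1	1	5	nuclear_AR_hom	NDUFA12	yes	.	.	.	yes	.
WB07	no	1	1	5	nuclear_AR_comphet	KARS	yes	.	.	.	yes	.
WB08	no	1	1	6	nuclear_AR_hom	NDUFV2	yes	.	.	.	yes	.
WB09	no	1	1	6	nuclear_AR_comphet	MTFMT	yes	.	.	.	yes	.
WB10	no	1	1	6	nuclear_AR_comphet	FBXL4	yes	.	.	.	yes	.
WB11	no	1	1	6	nuclear_AR_hom	C19orf12	no	.	depletion	.	yes	.
WB12	no	1	1	5	nuclear_AR_hom	TMEM126B	yes	.	.	.	yes	.
WB13	no	1	1	6	nuclear_AR_comphet	TRMU	yes	.	.	.	yes	.
WB14	no	1	1	7	nuclear_AR_hom	ATPAF2	yes	.	.	.	yes	.
WB15	no	1	1	7	nuclear_AR_hom	AMACR	yes	.	.	.	yes	.
WB16	no	1	1	5	nuclear_AR_hom	C12ORF65	yes	.	.	.	yes	.
WB17	no	1	1	7	nuclear_XLR	TAZ	no	.	.	M	yes	.
WB18	no	1	1	5	nuclear_AD_denovo	MFN2	yes	.	.	.	yes	.
WB19	no	1	1	5	nuclear_AD_inherited	C10orf2	yes	.	multiple_deletions	.	no	.
WB20	no	1	1	6	nuclear_AD_denovo;nuclear_AR_comphet	BICD2;HPS1	no;no	.	.	.	yes	.
WB21	no	1	1	7	nuclear_AR_comphet	IARS	no	.	.	.	yes	.
WB22	no	1	1	5	nuclear_AR_comphet	CHRNE	no	.	.	.	yes	.
GA01	yes	2	2	4	nuclear_AR_hom	CLPP	yes	.	.	.	yes	.
GA02	yes	1	2	4	nuclear_AR_hom	SLC25A32	yes	.	.	.	yes	.
GA03	yes	1	2	2	nuclear_AR_hom	CAPN3	no	.	.	.	yes	.
GA04	yes	1	2	2	nuclear_AR_hom	AP4M1	no	.	.	.	yes	.
GA05	yes	1	2	3	nuclear_AR_hom	ADD3	no	.	.	.	yes	.
GA06	yes	1	2	4	nuclear_AR_hom	LMOD3	no	.	.	.	yes	.
GA07	no	2	2	3	nuclear_AR_hom	LPIN1	no	.	.	.	yes	.
GA08	yes	2	2	4	nuclear_AR_hom	NBAS	no	.	.	.	yes	.
GA09	no	2	2	4	nuclear_AR_comphet	SCN4A	no	.	.	.	yes	.
GA10	yes	1	2	3	nuclear_AR_comphet	RELN	no	.	.	.	yes	.
GB01	no	1	2	4	nuclear_AR_hom;nuclear_AD_inherited	ACAD8;DNA2	yes;yes	.	multiple_deletions	.	yes	father
GB02	no	1	2	2	nuclear_AR_comphet	CWF19L1	no	.	.	.	yes	.
GB03	no	1	2	3	nuclear_AD_denovo	ACTA1	no	.	.	.	yes	.
GB04	no	1	2	4	nuclear_AD_denovo	PURA	no	.	.	.	yes	.
GB05	no	1	2	3	nuclear_AD_denovo	DYNC1H1	no	.	.	.	yes	.
GB06	no	1	2	5	nuclear_AD_denovo	CTNNB1	no	.	.	.	yes	.
GB07	no	1	2	5	nuclear_XLD_denovo	WDR45	no	.	.	F	yes	.
GB08	no	1	2	4	nuclear_XLD_denovo	CASK	no	.	.	F	yes	.
FA01	yes	1	1	6	none	.	.	.	.	.	yes	.
FA02	yes	1	1	6	none	.	.	.	.	.	yes	.
FA03	yes	1	1	6	none	.	.	.	.	.	yes	.
FA04	yes	1	1	6	none	.	.	.	.	.	yes	.
FA05	yes	1	1	6	none	.	.	.	.	.	yes	.
FA06	yes	1	1	6	none	.	.	.	.	.	yes	.
FA07	no	2	1	6	none	.	.	.	.	.	yes	.
FA08	no	2	1	6	none	.	.	.	.	.	yes	.
FA09	no	2	1	6	none	.	.	.	.	.	yes	.
FA10	yes	1	2	3	none	.	.	.	.	.	yes	.
FA11	yes	1	2	3	none	.	.	.	.	.	yes	.
FA12	yes	1	2	3	none	.	.	.	.	.	yes	.
FA13	no	2	2	3	none	.	.	.	.	.	yes	.
FB01	no	1	1	6	none	.	.	.	.	.	yes	.
FB02	no	1	1	6	none	.	.	.	.	.	yes	.
FB03	no	1	1	6	none	.	.	.	.	.	yes	.
FB04	no	1	1	6	none	.	.	.	.	.	yes	.
FB05	no	1	1	6	none	.	.	.	.	.	yes	.
FB06	no	1	1	6	none	.	.	.	.	.	yes	.
FB07	no	1	1	6	none	.	.	.	.	.	yes	.
FB08	no	1	1	6	none	.	.	.	.	.	yes	.
FB09	no	1	1	6	none	.	.	.	.	.	yes	.
FB10	no	1	1	6	none	.	.	.	.	.	yes	.
FB11	no	1	1	6	none	.	.	.	.	.	yes	.
FB12	no	1	1	6	none	.	.	.	.	.	yes	.
FB13	no	1	1	6	none	.	.	.	.	.	yes	.
FB14	no	1	1	6	none	.	.	.	.	.	yes	.
FB15	no	1	1	6	none	.	.	.	.	.	yes	.
FB16	no	1	2	3	none	.	.	.	.	.	yes	.
FB17	no	1	2	3	none	.	.	.	.	.	yes	.
FB18	no	1	2	3	none	.	.	.	.	.	yes	.
FB19	no	1	2	3	none	.	.	.	.	.	yes	.
FB20	no	1	2	3	none	.	.	.	.	.	yes	.
FB21	no	1	2	3	none	.	.	.	.	.	yes	.
FB22	no	1	2	3	none	.	.	.	.	.	yes	.
FB23	no	1	2	3	none	.	.	.	.	.	yes	.
FB24	no	1	2	3	none	.	.	.	.	.	yes	.
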