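domain	r2	ic_id	region	ba	network	b	ci_lo	ci_hi	p
visuospatial_executive	0.54	IC31	MTG	21	CCN	0.063	0.024	0.101	0.002
visuospatial_executive	0.54	IC49	MiFG	10	CCN	-0.060	-0.112	-0.009	0.024
visuospatial_executive	0.54	IC54	ITG	37	VIS	0.050	0.019	0.082	0.003
visuospatial_executive	0.54	IC47	Cerebellum	VI/VII/VIII	CBL	0.070	0.009	0.132	0.026
visuospatial_executive	0.54	IC56	SFG	8	CCN	-0.058	-0.112	-0.005	0.034
naming	0.39	IC25	SFG	8	DMN	-0.026	-0.043	-0.010	0.003
naming	0.39	IC48	MiFG	46	CCN	0.030	0.008	0.052	0.008
naming	0.39	IC14	Cuneus	30	VIS	-0.012	-0.023	-0.002	0.019
attention	0.86	IC49	MiFG	10	CCN	-0.059	-0.078	-0.039	<0.001
attention	0.86	IC71	STG	38	CCN	0.056	0.036	0.075	<0.001
attention	0.86	IC66	IFG	46	CCN	0.043	0.026	0.059	<0.001
attention	0.86	IC36	Cerebellum	VII	CBL	-0.027	-0.043	-0.011	0.002
attention	0.86	IC42	MiFG	6	SMN	0.028	0.016	0.040	<0.001
attention	0.86	IC15	MeFG	11	DMN	-0.031	-0.042	-0.020	0.005
attention	0.86	IC1	PrG	4	SMN	0.012	0.004	0.020	0.005
attention	0.86	IC54	ITG	37	VIS	0.020	0.008	0.032	0.002
attention	0.86	IC7	PoG	3	SMN	-0.025	-0.042	-0.008	0.005
attention	0.86	IC22	STG	38	CCN	-0.017	-0.032	-0.002	0.029
language	0.64	IC24	Uncus	20	CCN	-0.119	-0.159	-0.079	<0.001
language	0.64	IC3	CN		SCN	0.035	0.017	0.054	0.001
language	0.64	IC17	MeFG	8	DMN	-0.046	-0.067	-0.024	<0.001
language	0.64	IC23	STG	42	AUD	-0.036	-0.057	-0.015	0.001
language	0.64	IC62	MTG	19	VIS	0.054	0.009	0.098	0.020
language	0.64	IC35	MeFG	6	SMN	0.023	0.002	0.044	0.034
language	0.64	IC48	MiFG	46	CCN	0.033	0.001	0.065	0.043
abstraction	0.10	IC61	MiFG	10	CCN	-0.025	-0.049	0.000	0.047
delayed_recall	NA	NA	NA	NA	NA	NA	NA	NA	NA
orientation	0.64	IC49	MiFG	10	CCN	-0.050	-0.068	-0.031	<0.001
orientation	0.64	IC4	AC	32	DMN	-0.010	-0.016	-0.004	0.001
orientation	0.64	IC50	STG	38	CCN	0.034	0.016	0.052	<0.001
orientation	0.64	IC14	Cuneus	30	VIS	0.011	0.002	0.021	0.024
orientation	0.64	IC40	MeFG	6	SMN	-0.044	-0.083	-0.005	0.027
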