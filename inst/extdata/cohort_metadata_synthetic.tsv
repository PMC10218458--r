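patient_id	cohort	age	er_status	pr_status	her2_status	ihc_subtype	pt_stage	pn_stage
P01	adjuvant	32	positive	positive	negative	Luminal A	T1	pN0
P02	adjuvant	43	positive	positive	negative	Luminal A	T1	pN0
P03	adjuvant	44	positive	positive	negative	Luminal A	T1	pN0
P04	adjuvant	48	positive	positive	negative	Luminal A	T1	pN0
P05	adjuvant	49	positive	positive	negative	Luminal A	T2	pN0
P06	adjuvant	60	positive	positive	negative	Luminal A	T2	pN0
P07	adjuvant	60	positive	positive	negative	Luminal A	T2	pN0
P08	adjuvant	61	positive	positive	positive	Luminal B	T2	pN0
P09	adjuvant	61	positive	positive	negative	Luminal B	T2	pN0
P10	adjuvant	66	positive	positive	negative	Luminal B	T2	pN1
P11	adjuvant	67	positive	positive	negative	Luminal B	T2	pN1
P12	adjuvant	69	positive	negative	negative	Luminal B	T2	pN1
P13	adjuvant	69	positive	negative	negative	Luminal B	T2	pN2
P14	adjuvant	75	positive	negative	negative	Luminal B	T2	pN2
P15	adjuvant	80	positive	negative	negative	Luminal B	T3	pN3
P16	neoadjuvant	37	positive	positive	negative	Luminal B	T0	pN0
P17	neoadjuvant	43	positive	positive	negative	Luminal B	T0	pN0
P18	neoadjuvant	46	positive	positive	negative	Luminal B	T0	pN0
P19	neoadjuvant	47	positive	positive	negative	Luminal B	T0	pN0
P20	neoadjuvant	48	positive	positive	negative	Luminal B	T1	pN0
P21	neoadjuvant	51	positive	positive	negative	Luminal B	T1	pN0
P22	neoadjuvant	51	positive	negative	negative	Luminal B	T1	pN0
P23	neoadjuvant	56	positive	negative	negative	Luminal B	T1	pN1
P24	neoadjuvant	59	negative	negative	negative	Triple negative	T1	pN1
P25	neoadjuvant	63	negative	negative	negative	Triple negative	T2	pN1
P26	neoadjuvant	65	negative	negative	negative	Triple negative	T2	pN1
P27	neoadjuvant	66	negative	negative	negative	Triple negative	T2	pN1
P28	neoadjuvant	67	negative	negative	negative	Triple negative	T2	pN2
P29	neoadjuvant	67	negative	negative	negative	Triple negative	T3	pN3
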