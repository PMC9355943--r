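sample_id	steatosis	lobular_inflammation	fibrosis	bmi	age	sex
S001	1	1	1	26.6	50	F
S002	0	1	0	42.2	53	M
S003	1	1	1	51.8	47	F
S004	1	0	0	40	37	M
S005	2	1	1	36.7	43	M
S006	2	1	0	48.8	57	M
S007	1	2	1	37.4	41	M
S008	1	1	0	45.4	49	M
S009	2	0	0	30.5	53	M
S010	2	1	0	33	50	F
S011	2	1	1	40	44	M
S012	2	2	1	35.7	46	F
S013	2	1	1	53.5	37	F
S014	2	0	1	50.2	47	F
S015	0	0	0	37.6	37	F
S016	0	1	0	47.6	38	F
S017	1	1	0	50.2	37	M
S018	0	1	0	45.3	39	F
S019	0	1	1	46	52	M
S020	1	2	1	52.1	41	M
S021	1	1	1	39.8	43	F
S022	1	1	1	40.3	41	M
S023	1	2	0	50.5	48	F
S024	1	2	0	33.9	51	M
S025	1	2	1	44.8	42	M
S026	0	2	1	43.2	49	M
S027	2	0	0	46.9	41	F
S028	0	1	0	51	52	M
S029	2	1	1	45.4	49	M
S030	0	1	1	45.1	52	F
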