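voucher_id	life_stage	length_mm	morph_ecotype	pct_wrl
LayZolzap19Adult-S0001	adult	175	WBL	25.0
LayZolzap19Adult-S0010	adult	155	WBL	20.0
LayZolzap19Adult-S0011	adult	150	WBL	10.0
LayZolzap19Adult-S0012	adult	157	WBL	33.3
LayZolzap19Adult-S0014	adult	151	WBL	12.5
LayZolzap19Adult-S0015	adult	154	WBL	12.5
LayZolzap19Adult-S0016	adult	160	WBL	50.0
LayZolzap19Adult-S0017	adult	150	WBL	30.0
LayZolzap19Adult-S0018	adult	152	WBL	30.0
LayZolzap19Adult-S0021	adult	150	WBL	70.0
LriZolzap19Adult-B0001	adult	136	WBL	20.0
LriZolzap19Adult-B0002	adult	145	WBL	12.5
LriZolzap19Adult-B0003	adult	166	WBL	10.0
LriZolzap19Adult-B0005	adult	177	WBL	20.0
LriZolzap19Adult-B0006	adult	134	WBL	0.0
LriZolzap19Adult-B0010	adult	167	WBL	20.0
LriZolzap19Adult-B0011	adult	183	WBL	NA
LriZolzap19Adult-B0014	adult	151	WBL	NA
LriZolzap19Adult-B0016	adult	144	WBL	20.0
LriZolzap19Adult-B0017	adult	152	WBL	NA
LriZolzap19Adult-B0020	adult	175	WBL	33.3
LriZolzap19Adult-B0024	adult	153	WBL	10.0
LriZolzap19Adult-B0027	adult	122	WBL	0.0
LriZolzap19Adult-B0029	adult	149	WBL	37.5
LayZolzap19Adult-S0002	juvenile	156	WRL	100.0
LayZolzap19Adult-S0003	juvenile	183	WRL	80.0
LayZolzap19Adult-S0004	juvenile	161	WRL	100.0
LayZolzap19Adult-S0005	juvenile	149	WRL	50.0
LayZolzap19Adult-S0006	juvenile	147	WRL	100.0
LayZolzap19Adult-S0009	juvenile	157	WRL	80.0
LayZolzap19Adult-S0013	juvenile	158	WRL	100.0
LayZolzap19Adult-S0019	juvenile	166	WRL	30.0
LayZolzap19Adult-S0020	juvenile	171	WRL	NA
LriZolzap19Adult-B0012	adult	196	WRL	50.0
LriZolzap19Adult-B0018	adult	220	WRL	NA
LriZolzap19Adult-B0021	adult	217	WRL	NA
LriZolzap19Adult-B0022	adult	192	WRL	NA
LriZolzap19Adult-B0025	adult	205	WRL	100.0
LriZolzap19Adult-B0028	adult	200	WRL	100.0
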