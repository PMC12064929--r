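genetic	morph	count
WRL	WRL	101
WRL	unknown	54
WRL	WBL	1
Intermediate	WRL	2
Intermediate	unknown	7
Intermediate	WBL	3
WBL	WRL	3
WBL	unknown	172
WBL	WBL	171
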