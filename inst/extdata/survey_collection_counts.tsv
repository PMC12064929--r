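collection	region	site_code	year	n_entosphenus	n_lampetra_unknown	n_wbl	n_intermediate	n_wrl
1	Georgia Basin	GEORGS	2013-2019	0	1	0	0	90
2	Northern B.C.	ZOLZAP	2019	86	10	79	11	67
3	Northern B.C.	ZOLZAP	2020	43	0	19	5	32
4	WA coast	BINGHA	2019	1	1	9	0	0
5	WA coast	NEWAUK	2019	214	0	16	0	1
6	Estuarine LC	GRAYSR	2019	77	0	56	0	0
7	Estuarine LC	GRAYSR	2020	93	0	39	0	0
8	Estuarine LC	CZYJSN	2019	51	0	58	0	0
9	Estuarine LC	CZYJSN	2020	9	0	17	0	0
10	Estuarine LC	SKAMOK	2019	5	0	8	0	0
11	Mid LC	MILLCR	2019	20	0	27	1	0
12	Mid LC	MILLCR	2020	13	1	71	0	0
13	Mid LC	ABNTHY	2019	84	0	42	0	0
14	Mid LC	ABNTHY	2020	15	1	45	4	1
15	Mid LC	GERMAN	2019	62	0	19	0	0
16	Mid LC	GERMAN	2020	44	0	56	1	0
17	Upper LC	KALAMA	2019	13	0	0	0	0
18	Upper LC	COWLIT	2019	125	0	5	0	1
19	Upper LC	COWLIT	2020	61	0	7	0	0
20	Mid C	HAMILT	2019	9	0	6	0	0
21	Mid C	LWINDR	2019	12	0	9	0	0
22	Mid C	BIGWHS	2017	1	0	16	0	0
23	Mid C	BIGWHS	2018	0	1	21	0	0
24	Mid C	BIGWHS	2019	1	0	24	0	0
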