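category	Before	During	After	Continue	None	Total
O2	0	0	0	18	NA	18
Hypertension	405	1909	10	1405	NA	3729
Diabetes	60	57	13	877	NA	1007
Dyslipidemia	4	287	6	75	NA	372
CKD	0	0	0	26	NA	26
Atherosis	3	4	0	137	NA	144
OSAS	0	0	0	1	NA	1
Smoking	8	0	0	500	NA	508
A2	9	0	0	86	NA	95
FHCVD	0	0	0	10	NA	10
Age	NA	NA	NA	NA	1859	1859
Gender	NA	NA	NA	NA	1909	1909
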