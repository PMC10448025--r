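patient_id	series_id	sequence	region	operator	WL	WW	frame
P001	S0001	T1WI-SE	brain	1	593.7	536.5	native
P001	S0001	T1WI-SE	brain	2	543.7	683.5	native
P001	S0001	T1WI-SE	brain	3	746.5	541.2	native
P002	S0002	T2WI-TSE	pelvis	1	1233	1355.9	native
P002	S0002	T2WI-TSE	pelvis	2	1210.7	1532.5	native
P002	S0002	T2WI-TSE	pelvis	3	1391.7	1018.3	native
P003	S0003	T1WI-SE	brain	1	447.1	475.3	native
P003	S0003	T1WI-SE	brain	2	353.8	417.6	native
P003	S0003	T1WI-SE	brain	3	482.4	333.1	native
P004	S0004	T2WI-TSE	pelvis	1	446	517.8	native
P004	S0004	T2WI-TSE	pelvis	2	421.4	483.1	native
P004	S0004	T2WI-TSE	pelvis	3	494.7	384.4	native
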