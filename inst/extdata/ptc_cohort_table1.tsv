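patient_id	gender	age	tumor_cm	t	n	m	stage
1	female	41	1.00	T1	N1	M0	I
2	female	39	1.30	T1	N1	M0	I
3	female	37	2.00	T1	N1	M0	I
4	female	38	1.40	T1	N1	M0	I
5	female	57	1.20	T1	N0	M0	I
6	female	45	0.80	T1	N0	M0	I
7	female	41	1.50	T1	N0	M0	I
8	female	42	2.00	T1	N1	M0	I
9	female	29	1.50	T1	N1	M0	I
10	female	42	1.20	T1	N0	M0	I
11	female	47	0.80	T1	N0	M0	I
12	female	54	0.90	T1	N0	M0	I
13	female	61	1.80	T1	N0	M0	I
14	female	26	1.20	T1	N0	M0	I
15	female	49	0.70	T1	N0	M0	I
16	female	37	2.00	T4	N1	M0	I
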