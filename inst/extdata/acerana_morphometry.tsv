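indicator	group	mean	se	n
FL	SZ	8331.13	26.53	50
FL	WC	8074.91	27.68	50
FL	MK	8882.34	28.50	30
FB	SZ	2791.07	9.08	50
FB	WC	2735.01	9.07	50
FB	MK	3031.05	16.88	30
L6	SZ	2257.05	11.71	50
L6	WC	2153.16	10.91	50
L6	MK	2415.90	7.09	30
T6	SZ	2720.43	13.67	50
T6	WC	2523.80	10.81	50
T6	MK	2916.17	16.17	30
S3	SZ	2359.32	10.33	50
S3	WC	2221.33	8.87	50
S3	MK	2490.51	13.15	30
T3T4	SZ	3567.59	15.91	50
T3T4	WC	3415.16	16.41	50
T3T4	MK	3729.79	16.99	30
Fe	SZ	2329.92	12.12	50
Fe	WC	2267.87	7.95	50
Fe	MK	2504.20	21.66	30
Ti	SZ	2759.91	17.55	50
Ti	WC	2691.96	16.66	50
Ti	MK	3074.32	21.23	30
ML	SZ	1924.61	11.36	50
ML	WC	1853.14	9.20	50
ML	MK	2038.29	14.37	30
MT	SZ	1055.57	4.84	50
MT	WC	1040.64	6.15	50
MT	MK	1095.52	7.14	30
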