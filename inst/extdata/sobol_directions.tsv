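d	s	a	m
2	1	0	1
3	2	1	1 3
4	3	1	1 3 1
5	3	2	1 1 1
6	4	1	1 1 3 3
7	4	4	1 3 5 13
8	5	2	1 1 5 5 17
9	5	4	1 1 5 5 5
10	5	7	1 1 7 11 19
11	5	11	1 3 1 15 3
12	5	13	1 3 3 15 11
13	5	14	1 1 7 15 25
14	6	1	1 1 5 5 7 25
15	6	13	1 3 5 7 25 17
16	6	16	1 1 1 15 11 9
17	6	19	1 1 7 9 11 59
18	6	22	1 1 1 15 29 45
19	6	25	1 3 1 13 23 7
20	7	1	1 1 7 13 1 27 59
21	7	4	1 1 1 15 31 3 27
22	7	7	1 3 1 7 11 9 29
23	7	8	1 1 1 7 1 17 11
24	7	14	1 3 3 7 5 37 121
25	7	19	1 3 3 9 25 21 59
26	7	21	1 3 3 11 21 15 109
27	7	28	1 3 7 3 27 57 117
28	7	31	1 1 5 9 31 49 17
29	7	32	1 3 5 9 21 23 11
30	7	37	1 1 7 5 3 21 35
31	7	41	1 1 1 7 31 31 17
32	7	42	1 1 3 3 19 5 63
33	7	50	1 3 7 13 5 23 115
34	7	55	1 3 7 7 27 23 59
35	7	56	1 1 7 7 13 1 5
36	7	59	1 1 5 9 21 43 25
37	7	62	1 1 1 5 19 25 105
38	8	14	1 1 1 15 27 15 29 55
39	8	21	1 1 3 7 13 55 19 157
40	8	22	1 1 7 7 7 47 39 185
41	8	38	1 1 1 13 9 61 67 77
42	8	47	1 1 7 11 31 49 69 249
43	8	49	1 3 1 11 17 27 107 209
44	8	50	1 3 3 3 1 11 69 195
45	8	52	1 3 3 3 9 45 55 67
46	8	56	1 1 1 7 3 33 45 227
47	8	67	1 1 1 11 11 25 29 89
48	8	70	1 1 1 3 13 41 5 221
49	8	84	1 3 7 5 27 39 17 227
50	8	97	1 1 5 9 19 53 35 53
51	8	103	1 1 7 7 3 61 17 183
52	8	115	1 1 1 3 15 15 121 219
53	8	122	1 1 3 13 15 61 53 53
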