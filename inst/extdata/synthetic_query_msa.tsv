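pos	H	E	T	C
1	3	0	0	17
2	0	0	1	19
3	0	3	0	17
4	18	0	0	2
5	17	0	1	2
6	20	0	0	0
7	18	0	2	0
8	19	0	0	1
9	14	4	2	0
10	20	0	0	0
11	18	1	1	0
12	19	1	0	0
13	19	0	0	1
14	19	1	0	0
15	18	1	1	0
16	18	1	0	1
17	17	1	2	0
18	19	0	1	0
19	16	3	1	0
20	17	2	1	0
21	17	1	0	2
22	19	0	0	1
23	19	0	1	0
24	1	1	1	17
25	0	0	0	20
26	0	0	1	19
27	17	1	0	2
28	18	0	1	1
29	18	2	0	0
30	16	2	0	2
31	17	1	0	2
32	0	1	0	19
33	0	0	0	20
34	2	0	1	17
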