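serial	name	class
7	epap7	gv_specific
8	epap8	gv_specific
17	epap17	gv_specific
21	epap21	gv_specific
22	epap22	gv_specific
25	epap25	gv_specific
37	epap37	gv_specific
40	epap40	gv_specific
43	epap43	gv_specific
44	metalloproteinase	gv_specific
62	epap62	gv_specific
70	fgf-1	gv_specific
73	epap73	gv_specific
94	epap94	gv_specific
95	epap95	gv_specific
110	epap110	gv_specific
111	iap-5	gv_specific
126	epap126	gv_specific
131	fgf-3	gv_specific
4	epap4	unique
9	epap9	unique
12	epap12	unique
16	epap16	unique
18	epap18	unique
19	epap19	unique
20	epap20	unique
23	epap23	unique
49	epap49	unique
51	epap51	unique
60	epap60	unique
64	tmpk	unique
72	epap72	unique
89	epap89	unique
104	epap104	unique
114	epap114	unique
116	epap116	unique
91	lef-4	core
112	lef-9	core
122	lef-8	core
63	p47	core
82	lef-5	core
101	vlf-1	core
106	dnapol	core
68	lef-1	core
41	lef-2	core
85	helicase-1	core
81	p6.9	core
92	vp39	core
129	vp1054	core
96	vp91	core
99	gp41	core
29	odv-e18	core
59	p74	core
69	pif-1	core
47	pif-2	core
38	pif-3	core
84	pif-4	core
27	pif-5	core
109	pif-6	core
119	alk-exo	core
1	granulin	lepidopteran
113	25k-fp	lepidopteran
86	odv-e25	lepidopteran
80	bv/odv-c42	lepidopteran
14	f-protein	other
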