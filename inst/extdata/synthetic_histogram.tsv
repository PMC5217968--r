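bin	counts
1	16
2	14
3	10
4	12
5	15
6	9
7	20
8	33
9	59
10	111
11	162
12	232
13	316
14	416
15	447
16	485
17	506
18	483
19	444
20	417
21	431
22	389
23	379
24	367
25	347
26	280
27	291
28	259
29	264
30	273
31	212
32	227
33	240
34	216
35	185
36	193
37	179
38	189
39	183
40	183
41	179
42	187
43	168
44	126
45	137
46	126
47	125
48	133
49	131
50	115
51	107
52	97
53	93
54	121
55	110
56	93
57	101
58	104
59	90
60	99
61	87
62	104
63	94
64	82
65	74
66	82
67	89
68	81
69	81
70	78
71	77
72	64
73	80
74	74
75	75
76	84
77	79
78	64
79	79
80	84
81	58
82	64
83	65
84	63
85	70
86	72
87	65
88	71
89	57
90	57
91	61
92	79
93	67
94	74
95	63
96	49
97	52
98	60
99	66
100	55
101	63
102	43
103	57
104	55
105	56
106	54
107	64
108	61
109	47
110	58
111	55
112	48
113	49
114	51
115	56
116	42
117	47
118	43
119	56
120	43
121	41
122	55
123	36
124	41
125	37
126	46
127	41
128	45
129	51
130	53
131	31
132	34
133	50
134	41
135	40
136	38
137	41
138	44
139	44
140	37
141	51
142	37
143	47
144	38
145	38
146	37
147	51
148	50
149	36
150	38
151	36
152	52
153	41
154	40
155	45
156	36
157	39
158	44
159	33
160	35
161	37
162	30
163	37
164	35
165	32
166	25
167	28
168	26
169	36
170	38
171	24
172	34
173	32
174	34
175	38
176	33
177	34
178	25
179	30
180	35
181	25
182	32
183	24
184	32
185	36
186	32
187	20
188	41
189	33
190	30
191	28
192	29
193	27
194	34
195	33
196	31
197	28
198	26
199	29
200	26
201	27
202	26
203	29
204	20
205	23
206	31
207	31
208	22
209	31
210	23
211	26
212	27
213	19
214	22
215	16
216	23
217	25
218	31
219	24
220	20
221	23
222	21
223	22
224	29
225	19
226	20
227	25
228	19
229	22
230	22
231	33
232	23
233	24
234	17
235	23
236	19
237	17
238	19
239	19
240	15
241	17
242	20
243	13
244	27
245	15
246	23
247	18
248	16
249	15
250	21
251	22
252	18
253	23
254	17
255	20
256	15
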