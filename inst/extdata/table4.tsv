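# Stage-2 clinical cohort, commercial laboratory 2 (250 specimens), one row
# per printed result class; specimen ranges and per-sex counts as printed.
# Result strings transcribed verbatim (including the unicode minus in class
# 219 and the "icp.69, or XXY" class as printed).
specimens	n_female	n_male	icp_result
1-100	57	43	icp.46,XX or XY
101-107	7	0	icp.45,X
108-129	15	7	icp.47,XX or XY,+16
130-199	29	41	icp.47,XX or XY,+21
200-201	2	0	icp.92,XXYY
202	1	0	icp.92,XXXX/46,XX
203-213	3	8	icp.47,XX or XY,+13
214-218	4	1	icp.47,XX or XY,+18
219	1	0	icp.45,XY,−16
220-221	1	1	icp.47,XX or XY,+14
222-223	2	0	icp.47,XX,+15
224-225	2	0	icp.47,XX,+22
226	1	0	icp.47,XY,+4
227	1	0	icp.47,XX,+19
228	1	0	icp.47,XX,+20
229	1	0	icp.48,XX,+7,+16
230	1	0	icp.48,XX,+13,+16
231	1	0	icp.48,XXY,+15
232	1	0	icp.48,XXY,+16
233-234	1	1	icp.47,XXX or XXY
235	1	0	icp.46,XX,t(2;18)(p?;q?)
236	1	0	icp.46,XX,t(12;14)(p?;q?)
237	1	0	icp.46,XY,der(11)t(1;11)(q?;p?)
238-239	2	0	icp.46,XY,del(9)(p?)
240-241	2	0	icp.46,XY,del(16)(q?)
242	1	0	icp.47,XX,der(14;21),+21
243	1	0	icp.46,XX,der(4)t(4;21)(q?;q?)
244	1	0	icp.46,XX,del(10)(p?)
245-247	2	1	icp.69, or XXY
248	1	0	icp.47,XY,+8
249-250	1	1	icp.92,XXXX or XXYY
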