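node_id	label	parent	edge_sites	members	frequency
1	Y				0
2	C	1	rAX,rAY		0
3	T	2	rW		0
4	A	2	rA		0
5	H	2	fYR		0
6	Ta	3	fRL,fTY,fXT,fZK,fZW,sPZ		0
7	Tb	3	xTB		0
8	Ao-a	4	xAO		0
9	Ta-s	6	sPY		0
10	Ta-b	6	qGB,qGC		0
11	Tb-oB	7	xOB		0
12	Ao-aA	8	xAA		0
13	Ao-aD	8	xAD		0
14	Ta-bA	10	qDK		0
15	Tb-oB1	11	xOB1		0
16	Ao-aA1	12	xA1		0
17	Ao-aA3	12	xAA3		0
18	Ao-aD2	13	xAD2		0
19	Ao-aA1a	16	xA1A		0
20	Ao-aA1b	16	xA1B		0
21	Ao-aA1a1	19	xA1A1		0
22	Ao-aA1a2	19	xA1A2		0
23	Ao-aA1a3	19	xA1A3		0
24	Ao-aA1a4	19	rAB,fWO		0
25	Ao-aA1a5	19	xA1A5		0
26	Ao-aA1a2a	22	qFE		0
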