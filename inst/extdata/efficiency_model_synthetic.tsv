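# Synthetic positional-linear efficiency model (example/test coefficients,
# not trained on cleavage data). Columns: position nucleotide weight;
# position 1 = first context base (10-nt 5' flank precedes the spacer).
#intercept	0.2
11	G	0.02
11	C	0.02
11	A	-0.015
11	T	-0.015
12	G	0.02
12	C	0.02
12	A	-0.015
12	T	-0.015
13	G	0.02
13	C	0.02
13	A	-0.015
13	T	-0.015
14	G	0.02
14	C	0.02
14	A	-0.015
14	T	-0.015
15	G	0.02
15	C	0.02
15	A	-0.015
15	T	-0.015
16	G	0.02
16	C	0.02
16	A	-0.015
16	T	-0.015
17	G	0.02
17	C	0.02
17	A	-0.015
17	T	-0.015
18	G	0.02
18	C	0.02
18	A	-0.015
18	T	-0.015
19	G	0.02
19	C	0.02
19	A	-0.015
19	T	-0.015
20	G	0.02
20	C	0.02
20	A	-0.015
20	T	-0.015
21	G	0.02
21	C	0.02
21	A	-0.015
21	T	-0.015
22	G	0.02
22	C	0.02
22	A	-0.015
22	T	-0.015
23	G	0.02
23	C	0.02
23	A	-0.015
23	T	-0.015
24	G	0.02
24	C	0.02
24	A	-0.015
24	T	-0.015
25	G	0.02
25	C	0.02
25	A	-0.015
25	T	-0.015
26	G	0.02
26	C	0.02
26	A	-0.015
26	T	-0.015
27	G	0.02
27	C	0.02
27	A	-0.015
27	T	-0.015
28	G	0.02
28	C	0.02
28	A	-0.015
28	T	-0.015
29	G	0.02
29	C	0.02
29	A	-0.015
29	T	-0.015
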