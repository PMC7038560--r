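dinucleotide	Rise	Roll	Shift	Slide	Tilt	Twist
AA	3.27	0.7	-0.03	-0.08	-1.4	35.1
AC	3.36	0.7	0.13	-0.58	-0.1	31.5
AG	3.34	4.5	0.09	-0.25	-1.7	31.9
AT	3.31	1.1	0.00	-0.59	0.0	29.3
CA	3.33	4.7	0.09	0.53	0.5	37.3
CC	3.42	3.6	0.05	-0.22	-0.1	32.9
CG	3.39	5.4	0.00	0.41	0.0	36.1
CT	3.34	4.5	0.09	-0.25	-1.7	31.9
GA	3.37	1.9	-0.28	0.09	-1.5	36.3
GC	3.40	0.3	0.00	-0.38	0.0	33.6
GG	3.42	3.6	0.05	-0.22	-0.1	32.9
GT	3.36	0.7	0.13	-0.58	-0.1	31.5
TA	3.42	3.3	0.00	0.05	0.0	37.8
TC	3.37	1.9	-0.28	0.09	-1.5	36.3
TG	3.33	4.7	0.09	0.53	0.5	37.3
TT	3.27	0.7	-0.03	-0.08	-1.4	35.1
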