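fragment_size	frame0	frame1	frame2
24	15	15/12	18/12
25	15	12/15	18
26	15/12	18/15	18/15
27	15	15	18
28	15	15	18
29	15	15/18	18
30	15	18	18
31	15	18	18
32	18/15	18	18
33	18	18	18
34	18	18	18/21
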