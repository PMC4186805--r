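partition	pos	chain	pct_T	pct_C	pct_A	pct_G	pct_AT	at_skew	gc_skew
PCG	1	J	28.1	13.2	42.9	15.8	73.0	0.21	0.09
PCG	1	N	47.0	7.4	27.1	18.4	74.1	-0.27	0.43
PCG	2	J	45.3	20.3	21.4	13.0	66.7	-0.36	-0.22
PCG	2	N	50.6	13.8	18.9	16.7	69.5	-0.46	0.10
PCG	3	J	26.5	12.1	59.6	1.7	86.1	0.38	-0.75
PCG	3	N	62.2	2.0	24.8	11.0	87.0	-0.43	0.69
tRNA	-	J	35.6	9.5	44.4	10.4	80.0	0.11	0.05
tRNA	-	N	35.0	14.1	43.4	7.5	78.4	0.11	0.31
rRNA	-	N	49.7	7.0	30.0	13.3	79.7	-0.25	0.31
AT_rich	-	J	38.0	10.9	43.6	7.5	81.6	0.07	0.18
genome	-	J	29.9	14.7	46.5	8.8	76.4	0.22	0.29
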