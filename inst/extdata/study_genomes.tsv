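species	location	size_bp	at_pct	at_skew	gc_skew	accession
A. contigua	Henan	15613	76.3	0.216	-0.249	JX844626
A. producta	Guizhou	15227	77.4	0.204	-0.233	GQ337955
C. biformis	Yunnan	15222	76.8	0.203	-0.264	JX844627
C. braconoides	Yunnan	15637	77.2	0.189	-0.214	JX844628
C. versicolor	Henan	15374	75.8	0.230	-0.286	EU725832
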