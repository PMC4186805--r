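pair	atrich_k2p	cox1_k2p	atp8_k2p
C.braconoides_vs_C.biformis	0.318	0.112	0.173
A.contigua_vs_A.producta	0.609	0.093	0.127
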