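gene	strand	pam	k2p_total	k2p_pos1	k2p_pos2	k2p_pos3	ti_tv	ka_ks
atp8	J	0.408	0.237	0.176	0.141	0.434	0.8	0.3487
atp6	J	0.149	0.160	0.135	0.061	0.307	1.1	0.1679
cox1	J	0.041	0.132	0.076	0.011	0.355	1.7	0.0383
cox2	J	0.076	0.140	0.093	0.026	0.346	1.7	0.0578
cox3	J	0.118	0.152	0.101	0.049	0.342	1.5	0.1074
cytb	J	0.139	0.165	0.116	0.039	0.385	1.1	0.1187
nad2	J	0.256	0.195	0.197	0.098	0.307	0.9	0.2930
nad3	J	0.179	0.164	0.123	0.074	0.320	0.9	0.2114
nad6	J	0.241	0.182	0.140	0.119	0.303	1.2	0.2599
nad1	N	0.163	0.150	0.105	0.045	0.339	1.2	0.1501
nad4	N	0.171	0.140	0.097	0.058	0.286	1.0	0.1993
nad4l	N	0.208	0.175	0.161	0.049	0.350	1.0	0.2572
nad5	N	0.235	0.177	0.147	0.084	0.321	0.9	0.2412
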