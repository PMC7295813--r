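condition	a_T	b_T	a_v	b_v	L_um	tau_s	cluster_slope	dc_reference_um
control	2.5e-2	39	1.6e-2	-1.3	6.1	0.46	0.25	85
alpha_actinin	1.8e-3	45	1.9e-2	-1.1	6.1	0.09	0.31	115
gelsolin	1.5e-2	38	1.9e-2	-1.4	4.3	0.46	0.29	60
mdia2	2.7e-2	34	2.4e-2	-3.1	10	0.46	0.31	138
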