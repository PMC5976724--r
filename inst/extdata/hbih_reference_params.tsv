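C_m	T	g_d	g_r	g_sd	g_sr	g_l	g_h	V0_d	V0_r	V0_sd	V0_h	s_d	s_r	s_sd	s_h	tau_r	tau_sd	tau_sr	tau_h	eta	kappa	E_d	E_r	E_sd	E_sr	E_l	E_h
1	36	2.5	2.8	0.21	0.28	0.06	0.4	-25	-25	-40	-85	0.25	0.25	0.11	-0.14	2	10	35	125	0.014	0.18	50	-90	50	-90	-80	-30
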