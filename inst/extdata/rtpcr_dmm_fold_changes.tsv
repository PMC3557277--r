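gene	fold_change_2wk	p_value_2wk	fold_change_4wk	p_value_4wk	fold_change_8wk	p_value_8wk	fold_change_16wk	p_value_16wk
Adamts5	0.37	NA	0.26	NA	0.86	NA	0.96	NA
Aggrecan	2.53	NA	5.90	0.006	1.06	NA	2.00	NA
Asporin	1.45	NA	2.50	0.04	1.60	0.05	2.00	NA
Ccl21	1.48	NA	2.41	0.001	2.27	0.003	1.57	0.05
Ccr7	0.48	0.006	1.00	NA	1.83	0.05	1.00	NA
Cxcr7	2.43	NA	2.77	0.03	1.51	0.02	2.99	0.03
Col3	2.24	0.05	4.28	NA	1.93	NA	3.34	0.004
Col10	0.48	0.02	0.25	NA	1.75	NA	1.17	NA
Dkk3	4.27	0.01	2.50	0.02	1.77	NA	2.50	NA
Htra1	1.39	NA	4.09	0.01	1.81	0.008	3.00	NA
Igf1	1.88	NA	3.50	0.0004	3.00	0.002	3.00	0.008
Il33	1.50	NA	1.50	NA	1.61	0.05	1.88	NA
Mmp3	3.68	0.03	10.57	NA	2.32	0.007	2.22	NA
Mmp13	1.48	NA	2.00	NA	1.08	NA	1.46	NA
Periostin	4.48	NA	3.38	0.009	1.44	NA	1.75	NA
Sfrp2	2.92	0.01	2.81	0.002	1.56	0.01	1.29	NA
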