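lg	name	peak_cm	mean_r2	start_cm	end_cm	start_bp	end_bp	n_candidates	n_qtls	n_studies
1	ver_1.1	31.29	0.11	29.15	33.43	2510506	3254952	78	2	2
2	ver_2.1	31.34	0.17	28.79	33.89	4029921	5344816	147	7	2
2	ver_2.2	41.55	0.13	40.00	43.30	5717649	7154894	96	5	3
2	ver_2.3	53.47	0.34	52.88	54.07	13336750	16677137	94	5	3
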