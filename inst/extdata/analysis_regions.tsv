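name	ppm_lo	ppm_hi	role
R01_gap_0.50_0.60	0.50	0.60	analysis_region
R02_Cholesterol	0.60	0.75	analysis_region
R03_gap_0.75_0.80	0.75	0.80	analysis_region
R04_Lipid_CH3	0.80	0.90	analysis_region
R05_gap_0.90_0.92	0.90	0.92	analysis_region
R06_Isoleucine_Leucine	0.92	0.97	analysis_region
R07_gap_0.97_0.98	0.97	0.98	analysis_region
R08_Isoleucine_Valine	0.98	1.00	analysis_region
R09_gap_1.00_1.03	1.00	1.03	analysis_region
R10_Valine	1.03	1.05	analysis_region
R11_gap_1.05_1.20	1.05	1.20	analysis_region
R12_Lipids_CH2n	1.20	1.32	analysis_region
R13_Lactate	1.32	1.35	analysis_region
R14_gap_1.35_1.46	1.35	1.46	analysis_region
R15_Alanine	1.46	1.49	analysis_region
R16_gap_1.49_1.55	1.49	1.55	analysis_region
R17_Lipids_bCH2	1.55	1.60	analysis_region
R18_gap_1.60_1.92	1.60	1.92	analysis_region
R19_Isoleucine	1.92	1.97	analysis_region
R20_gap_1.97_1.98	1.97	1.98	analysis_region
R21_Aminobutyrate_CH2	1.98	2.03	analysis_region
R22_gap_2.03_2.10	2.03	2.10	analysis_region
R23_N_acetylglutamine	2.10	2.15	analysis_region
R24_gap_2.15_2.34	2.15	2.34	analysis_region
R25_Pyruvate+OH_isovalerate	2.34	2.38	analysis_region
R26_OH_isovalerate	2.38	2.41	analysis_region
R27_gap_2.41_2.43	2.41	2.43	analysis_region
R28_Glutamine	2.43	2.47	analysis_region
R29_gap_2.47_2.65	2.47	2.65	analysis_region
R30_Dimethylamine	2.65	2.80	analysis_region
R31_gap_2.80_2.90	2.80	2.90	analysis_region
R32_Trimethylamine	2.90	2.95	analysis_region
R33_Albumin	2.95	3.00	analysis_region
R34_gap_3.00_3.02	3.00	3.02	analysis_region
R35_Creatine_CreatineP	3.02	3.05	analysis_region
R36_gap_3.05_3.18	3.05	3.18	analysis_region
R37_Choline	3.18	3.20	analysis_region
R38_gap_3.20_3.21	3.20	3.21	analysis_region
R39_O_Phosphocholine	3.21	3.22	analysis_region
R40_gap_3.22_3.32	3.22	3.32	analysis_region
R41_Proline	3.32	3.37	analysis_region
R42_gap_3.37_3.45	3.37	3.45	analysis_region
R43_Glucose	3.45	3.48	analysis_region
R44_gap_3.48_3.68	3.48	3.68	analysis_region
R45_Leucine	3.68	3.72	analysis_region
R46_gap_3.72_3.93	3.72	3.93	analysis_region
R47_Creatine_P	3.93	3.97	analysis_region
R48_gap_3.97_4.03	3.97	4.03	analysis_region
R49_Creatinine	4.03	4.08	analysis_region
R50_gap_4.08_4.40	4.08	4.40	analysis_region
R51_gap_4.40_4.70	4.40	4.70	analysis_region
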