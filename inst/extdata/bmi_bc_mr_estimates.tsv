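group	outcome	exposure	n_snp	ivw_beta	ivw_se	ivw_pval	ivw_q	ivw_bonf	wm_beta	wm_se	wm_pval	egger_beta	egger_se	egger_pval	q_stat	q_pval	egger_intercept	egger_intercept_se	egger_intercept_pval	presso_raw_beta	presso_raw_sd	presso_raw_pval	presso_corr_beta	presso_corr_sd	presso_corr_pval
The impact of female body mass index on Breast cancer	Breast cancer	Body mass index || id:ieu-a-974	34	-1.84E-01	6.02E-02	2.21E-03	3.32E-03	6.63E-03	-1.61E-01	6.32E-02	1.06E-02	-4.13E-01	1.84E-01	3.22E-02	8.95E+01	4.12E-07	8.17E-03	6.23E-03	1.99E-01	-1.84E-01	6.02E-02	4.37E-03	-2.02E-01	5.77E-02	1.38E-03
The impact of female body mass index on Breast cancer	ER+ Breast cancer	Body mass index || id:ieu-a-974	35	-1.83E-01	6.40E-02	4.28E-03	4.28E-03	1.28E-02	-1.68E-01	6.56E-02	1.05E-02	-2.66E-01	2.04E-01	2.01E-01	7.64E+01	4.21E-05	2.98E-03	6.93E-03	6.70E-01	-1.83E-01	6.40E-02	7.25E-03	-1.80E-01	5.78E-02	3.86E-03
The impact of female body mass index on Breast cancer	ER- Breast cancer	Body mass index || id:ieu-a-974	35	-3.49E-01	9.76E-02	3.43E-04	1.03E-03	1.03E-03	-3.70E-01	1.03E-01	3.07E-04	-6.02E-01	3.09E-01	6.00E-02	7.61E+01	4.57E-05	9.01E-03	1.05E-02	3.95E-01	-3.49E-01	9.76E-02	1.06E-03	-3.46E-01	8.97E-02	5.16E-04
The impact of female body mass index (GIANT consortium ID:ieu-a-974/ID:ieu-a-95) on sex hormones	Bioavailable testosterone levels || id:ebi-a-GCST90012102	Body mass index || id:ieu-a-974	37	1.23E-01	1.61E-02	2.05E-14	8.20E-14	8.20E-14	1.00E-01	2.15E-02	3.09E-06	4.25E-02	4.19E-02	3.17E-01	5.65E+01	1.59E-02	3.18E-03	1.53E-03	4.49E-02	1.23E-01	1.61E-02	4.73E-09	NA	NA	NA
The impact of female body mass index (GIANT consortium ID:ieu-a-974/ID:ieu-a-95) on sex hormones	Estradiol levels || id:ebi-a-GCST90020092	Body mass index || id:ieu-a-974	29	-7.35E-02	7.16E-02	3.04E-01	3.46E-01	1	-4.01E-02	1.01E-01	6.92E-01	4.88E-02	1.90E-01	8.00E-01	3.24E+01	2.57E-01	-5.07E-03	7.30E-03	4.93E-01	-7.35E-02	7.16E-02	3.13E-01	NA	NA	NA
The impact of female body mass index (GIANT consortium ID:ieu-a-974/ID:ieu-a-95) on sex hormones	Sex hormone-binding globulin levels || id:ebi-a-GCST90012107	Body mass index || id:ieu-a-974	34	-8.54E-02	1.36E-02	2.94E-10	5.88E-10	1.18E-09	-9.81E-02	1.35E-02	4.30E-13	-8.02E-02	4.38E-02	7.68E-02	8.95E+01	4.07E-07	-1.86E-04	1.47E-03	9.00E-01	-8.54E-02	1.36E-02	3.98E-07	-9.11E-02	1.19E-02	1.07E-08
The impact of female body mass index (GIANT consortium ID:ieu-a-974/ID:ieu-a-95) on sex hormones	Total testosterone levels || id:ebi-a-GCST90012112	Body mass index || id:ieu-a-974	37	2.33E-02	2.48E-02	3.46E-01	3.46E-01	1	-3.12E-03	2.36E-02	8.95E-01	-8.01E-02	6.54E-02	2.29E-01	1.09E+02	3.29E-09	4.07E-03	2.39E-03	9.78E-02	2.33E-02	2.48E-02	3.52E-01	2.49E-02	1.97E-02	2.14E-01
The impact of female body mass index (GIANT consortium ID:ieu-a-974/ID:ieu-a-95) on sex hormones	Bioavailable testosterone levels || id:ebi-a-GCST90012102	Body mass index || id:ieu-a-95	11	1.18E-01	1.93E-02	9.41E-10	NA	NA	1.12E-01	2.40E-02	3.00E-06	3.82E-02	7.56E-02	6.25E-01	1.32E+01	2.13E-01	4.26E-03	3.89E-03	3.02E-01	1.18E-01	1.93E-02	1.13E-04	NA	NA	NA
The impact of sex hormones on Breast cancer	Breast cancer	Bioavailable testosterone levels || id:ebi-a-GCST90012102	124	1.45E-01	4.55E-02	1.40E-03	2.80E-03	5.61E-03	2.97E-02	4.62E-02	5.21E-01	1.92E-01	9.07E-02	3.64E-02	3.79E+02	8.11E-28	-1.47E-03	2.48E-03	5.54E-01	1.45E-01	4.55E-02	1.78E-03	1.59E-01	3.99E-02	1.15E-04
The impact of sex hormones on Breast cancer	Breast cancer	Estradiol levels || id:ebi-a-GCST90020092	2	3.46E-01	1.96E-01	7.75E-02	1.03E-01	3.10E-01	NA	NA	NA	NA	NA	NA	1.01E+01	1.52E-03	NA	NA	NA	NA	NA	NA	NA	NA	NA
The impact of sex hormones on Breast cancer	Breast cancer	Sex hormone-binding globulin levels || id:ebi-a-GCST90012107	196	-7.60E-02	5.41E-02	1.60E-01	1.60E-01	6.40E-01	-1.68E-02	6.01E-02	7.79E-01	8.11E-03	9.51E-02	9.32E-01	5.45E+02	6.76E-35	-1.75E-03	1.62E-03	2.84E-01	-7.60E-02	5.41E-02	1.62E-01	-6.00E-02	4.99E-02	2.30E-01
The impact of sex hormones on Breast cancer	Breast cancer	Total testosterone levels || id:ebi-a-GCST90012112	196	1.25E-01	2.56E-02	9.82E-07	3.93E-06	3.93E-06	1.18E-01	3.16E-02	1.91E-04	1.90E-01	5.24E-02	3.78E-04	4.05E+02	7.80E-17	-2.35E-03	1.67E-03	1.61E-01	1.25E-01	2.56E-02	2.05E-06	1.30E-01	2.36E-02	1.14E-07
The impact of sex hormones on ER+ breast cancer	ER+ Breast cancer	Bioavailable testosterone levels || id:ebi-a-GCST90012102	126	2.01E-01	5.28E-02	1.35E-04	2.70E-04	5.41E-04	1.52E-01	5.70E-02	7.56E-03	2.45E-01	1.05E-01	2.15E-02	3.66E+02	1.83E-25	-1.36E-03	2.85E-03	6.34E-01	2.01E-01	5.28E-02	2.12E-04	2.15E-01	4.51E-02	5.11E-06
The impact of sex hormones on ER+ breast cancer	ER+ Breast cancer	Estradiol levels || id:ebi-a-GCST90020092	2	3.99E-01	1.30E-01	2.13E-03	2.84E-03	8.51E-03	NA	NA	NA	NA	NA	NA	3.08E+00	7.92E-02	NA	NA	NA	NA	NA	NA	NA	NA	NA
The impact of sex hormones on ER+ breast cancer	ER+ Breast cancer	Sex hormone-binding globulin levels || id:ebi-a-GCST90012107	197	-1.06E-01	6.10E-02	8.36E-02	8.36E-02	3.34E-01	-2.97E-02	6.84E-02	6.64E-01	-2.76E-02	1.07E-01	7.97E-01	4.92E+02	1.85E-27	-1.62E-03	1.83E-03	3.77E-01	-1.06E-01	6.10E-02	8.52E-02	-1.05E-01	5.68E-02	6.50E-02
The impact of sex hormones on ER+ breast cancer	ER+ Breast cancer	Total testosterone levels || id:ebi-a-GCST90012112	196	1.72E-01	2.89E-02	2.70E-09	1.08E-08	1.08E-08	1.61E-01	3.73E-02	1.53E-05	2.59E-01	5.90E-02	1.81E-05	3.63E+02	3.11E-12	-3.19E-03	1.88E-03	9.07E-02	1.72E-01	2.89E-02	1.23E-08	1.83E-01	2.78E-02	3.71E-10
The impact of sex hormones on ER- breast cancer	ER- Breast cancer	Bioavailable testosterone levels || id:ebi-a-GCST90012102	126	-3.60E-02	6.89E-02	6.02E-01	6.02E-01	1	1.20E-02	8.72E-02	8.90E-01	1.45E-01	1.36E-01	2.90E-01	2.66E+02	2.89E-12	-5.66E-03	3.69E-03	1.27E-01	-3.60E-02	6.89E-02	6.03E-01	-2.42E-02	5.89E-02	6.82E-01
The impact of sex hormones on ER- breast cancer	ER- Breast cancer	Estradiol levels || id:ebi-a-GCST90020092	2	2.52E-01	4.16E-01	5.44E-01	6.02E-01	1	NA	NA	NA	NA	NA	NA	1.38E+01	2.03E-04	NA	NA	NA	NA	NA	NA	NA	NA	NA
The impact of sex hormones on ER- breast cancer	ER- Breast cancer	Sex hormone-binding globulin levels || id:ebi-a-GCST90012107	198	8.64E-02	7.79E-02	2.68E-01	6.02E-01	1	2.45E-01	1.06E-01	2.08E-02	1.62E-01	1.38E-01	2.40E-01	3.46E+02	2.75E-10	-1.56E-03	2.34E-03	5.05E-01	8.64E-02	7.79E-02	2.69E-01	7.43E-02	7.57E-02	3.28E-01
The impact of sex hormones on ER- breast cancer	ER- Breast cancer	Total testosterone levels || id:ebi-a-GCST90012112	198	-2.03E-02	3.63E-02	5.75E-01	6.02E-01	1	8.75E-03	5.55E-02	8.75E-01	1.90E-02	7.47E-02	8.00E-01	2.49E+02	6.79E-03	-1.42E-03	2.36E-03	5.47E-01	-2.03E-02	3.63E-02	5.76E-01	-2.56E-02	3.53E-02	4.70E-01
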