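mediator	exposure	step1_n_snp	step1_beta	step1_se	step1_pval	step1_q	step1_egger_intercept	step1_egger_se	step1_egger_pval	outcome	step2_n_snp	step2_beta	step2_se	step2_pval	step2_q	step2_egger_intercept	step2_egger_se	step2_egger_pval	z	indirect
Ratio of docosahexaenoic acid to total fatty acid levels || id:ebi-a-GCST90092817	Body mass index || id:ieu-a-974	37	-0.085086449	0.027155212	0.001728305	0.003073914	-0.003304708	0.002670168	0.224087977	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	28	0.091509172	0.043974997	0.037439727	0.561723713	-0.000929276	0.004886817	0.850660886	-1.677960732	-0.00778619
Glycine levels || id:ebi-a-GCST90092820	Body mass index || id:ieu-a-974	37	-0.10282217	0.021862485	2.56E-06	1.01E-05	0.001608154	0.002179492	0.465519909	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	40	0.047285359	0.022330825	0.034218052	0.561723713	-0.001322072	0.002817981	0.641639042	-1.957639942	-0.004861983
Cholesteryl ester levels in HDL || id:ebi-a-GCST90092823	Body mass index || id:ieu-a-974	34	-0.173433271	0.03502089	7.33E-07	3.65E-06	-0.003309471	0.003487492	0.349755825	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	76	0.082791041	0.040150917	0.039208093	0.561723713	0.003861805	0.003687104	0.298332557	-2.073782585	-0.014358721
Free cholesterol to total lipids ratio in IDL || id:ebi-a-GCST90092836	Body mass index || id:ieu-a-974	37	-0.069114589	0.030894472	0.025278611	0.035967853	-0.000135205	0.00310351	0.965498605	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	49	0.09402693	0.040339359	0.019758741	0.561723713	-0.003253847	0.003615251	0.372691076	-1.493008824	-0.006498633
Cholesterol levels in large HDL || id:ebi-a-GCST90092844	Body mass index || id:ieu-a-974	33	-0.211846231	0.024722028	1.04E-17	8.65E-16	-0.003711157	0.002374461	0.128217192	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	94	0.065129434	0.032386192	0.044322844	0.561723713	-0.000840383	0.002822204	0.766545961	-2.443722075	-0.013797425
Cholesteryl ester levels in large HDL || id:ebi-a-GCST90092846	Body mass index || id:ieu-a-974	33	-0.214121746	0.02510269	1.47E-17	9.12E-16	-0.003614961	0.002418553	0.145108841	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	95	0.075590332	0.032005456	0.018186688	0.561723713	0.000169479	0.002758236	0.951136992	-2.745915426	-0.016185534
Cholesteryl esters to total lipids ratio in large HDL || id:ebi-a-GCST90092847	Body mass index || id:ieu-a-974	35	-0.183038567	0.033628091	5.24E-08	5.43E-07	-0.001958767	0.003367782	0.564775409	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	69	0.08922574	0.039608775	0.024279581	0.561723713	0.002868	0.003491915	0.414373817	-2.301000653	-0.016331752
Concentration of large HDL particles || id:ebi-a-GCST90092851	Body mass index || id:ieu-a-974	33	-0.210683268	0.023819901	9.17E-19	2.28E-16	-0.0039512	0.002267858	0.091377589	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	87	0.069087353	0.033676737	0.040219647	0.561723713	0.000560428	0.003008939	0.852688989	-2.631365618	-0.014555549
Phospholipids to total lipids ratio in medium HDL || id:ebi-a-GCST90092901	Body mass index || id:ieu-a-974	34	0.170200915	0.033523685	3.83E-07	2.39E-06	0.002192949	0.003363125	0.519020883	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	74	-0.105247809	0.041571684	0.011350501	0.561723713	0.000643638	0.003883769	0.868837702	-2.491339754	-0.017913273
Ratio of monounsaturated fatty acids to total fatty acids || id:ebi-a-GCST90092929	Body mass index || id:ieu-a-974	37	0.147290827	0.029238512	4.71E-07	2.67E-06	0.004931765	0.002816395	0.088691087	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	61	-0.073292722	0.037001943	0.04761591	0.561723713	0.00343941	0.003609895	0.344592297	-2.121171564	-0.010795346
Ratio of polyunsaturated fatty acids to monounsaturated fatty acids || id:ebi-a-GCST90092940	Body mass index || id:ieu-a-974	37	-0.132481572	0.028274045	2.79E-06	1.07E-05	-0.004627115	0.002730537	0.099036462	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	53	0.089878071	0.040032576	0.024760214	0.561723713	0.000558915	0.003987194	0.889071855	-2.292519887	-0.011907188
Triglyceride levels in small HDL || id:ebi-a-GCST90092954	Body mass index || id:ieu-a-974	37	0.100675652	0.030480432	0.0009567	0.001832449	0.004031473	0.002984989	0.185497634	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	63	-0.067687141	0.03317738	0.041334459	0.561723713	-0.00268831	0.003696587	0.469860299	-1.792058299	-0.006814447
Total triglycerides levels || id:ebi-a-GCST90092992	Body mass index || id:ieu-a-974	37	0.070282804	0.022789316	0.002042209	0.00353132	0.001705823	0.002271135	0.457620132	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	63	-0.082380519	0.034045418	0.015532287	0.561723713	-0.003607102	0.003347716	0.285507887	-1.792655809	-0.005789934
Triglyceride levels in VLDL || id:ebi-a-GCST90093003	Body mass index || id:ieu-a-974	37	0.075888196	0.022581284	0.000777543	0.001548865	0.002050699	0.002241845	0.366588931	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	61	-0.074643114	0.03798932	0.049432216	0.561723713	-0.00219581	0.003649829	0.549731991	-1.709672427	-0.005664531
Triglycerides to total lipids ratio in very large HDL || id:ebi-a-GCST90093015	Body mass index || id:ieu-a-974	37	0.139560841	0.032175611	1.44E-05	4.49E-05	0.00441667	0.003144588	0.168973719	ER- Breast cancer (Combined Oncoarray; iCOGS; GWAS meta-analysis) || id:ieu-a-1128	62	-0.074768727	0.033066903	0.023750908	0.561723713	0.000290243	0.003709974	0.937903007	-2.035622767	-0.010434786
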