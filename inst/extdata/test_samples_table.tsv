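serial	lab_conc_mgdl	alpha	beta	i492	i468	predicted_mgdl
1	9.6	-0.0476	NA	0.12161	NA	8.86
2	9.1	-3.6952e-4	NA	0.14443	NA	9.43
3	6.41	0.04074	NA	0.12773	NA	9.02
4	9.2	0.00209	NA	0.21509	NA	10.67
5	6.4	-0.02099	NA	0.05157	NA	6.61
6	8.9	-0.06989	NA	0.10838	NA	8.49
7	14.4	-0.01421	0.00322	NA	0.13154	19.75
8	12.1	0.04826	7.30125e-4	NA	0.03963	12.86
9	10.2	0.02115	8.66687e-4	NA	0.01175	10.51
10	12.6	0.01246	6.00172e-4	NA	0.02351	11.52
11	11.7	0.06474	4.30757e-4	NA	0.01832	11.07
12	12.1	0.05962	1.91689e-4	NA	0.02969	12.04
13	12.5	0.04656	2.7896e-4	NA	0.02845	11.93
14	11	0.08559	2.7938e-4	NA	0.0185	11.09
15	13.3	0.01692	1.39385e-4	NA	0.05925	14.44
16	11.3	0.10341	1.81991e-4	NA	0.01929	11.16
17	12.7	0.01455	6.95115e-4	NA	0.0338	12.38
18	21.5	0.05585	0.0014	NA	NA	NA
19	19	0.23111	0.00214	NA	NA	NA
20	15.6	0.028	0.00135	NA	NA	NA
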