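snp_id	trait	trait_raising_allele	beta	ref_allele_freq	chromosome	position	ref_allele	alt_allele
rs9000001	LDL	A	0.15365	0.732	chr1	50100000	A	T
rs9000002	LDL	T	0.075297	0.247	chr15	50200000	A	T
rs9000003	LDL	G	0.112826	0.491	chr8	50300000	T	G
rs9000004	LDL	A	0.099295	0.429	chr2	50400000	C	A
rs9000005	LDL	T	0.064402	0.826	chr22	50500000	T	G
rs9000006	LDL	A	0.107914	0.511	chr14	50600000	A	T
rs9000007	LDL	G	0.17331	0.585	chr13	50700000	G	T
rs9000008	LDL	A	0.060466	0.55	chr22	50800000	A	G
rs9000009	LDL	T	0.067919	0.376	chr16	50900000	C	T
rs9000010	LDL	G	0.098837	0.819	chr5	5.1e+07	G	A
rs9000011	TG	C	0.115381	0.205	chr11	51100000	T	C
rs9000012	TG	A	0.035034	0.238	chr3	51200000	G	A
rs9000013	TG	A	0.089645	0.332	chr11	51300000	A	G
rs9000014	TG	A	0.094447	0.366	chr22	51400000	A	G
rs9000015	TG	T	0.101572	0.452	chr16	51500000	T	C
rs9000016	TG	C	0.105287	0.71	chr18	51600000	C	A
rs9000017	TG	T	0.119236	0.394	chr16	51700000	T	C
rs9000018	TG	A	0.075876	0.346	chr10	51800000	T	A
rs9000019	TG	G	0.031634	0.6	chr3	51900000	C	G
rs9000020	TG	C	0.097566	0.487	chr2	5.2e+07	C	A
rs9000021	TG	C	0.068403	0.513	chr8	52100000	T	C
rs9000022	TG	G	0.043069	0.27	chr19	52200000	C	G
rs9000023	TG	C	0.118848	0.419	chr13	52300000	C	A
rs9000024	TG	T	0.038038	0.736	chr22	52400000	T	G
rs9000025	TG	G	0.030805	0.524	chr21	52500000	T	G
rs9000026	TG	G	0.103219	0.689	chr3	52600000	C	G
rs9000027	HDL	A	0.028962	0.234	chr1	52700000	A	T
rs9000028	HDL	G	0.014506	0.19	chr13	52800000	A	G
rs9000029	HDL	C	0.03116	0.675	chr19	52900000	C	G
rs9000030	HDL	A	0.035781	0.245	chr16	5.3e+07	A	C
rs9000031	HDL	C	0.034887	0.345	chr16	53100000	G	C
rs9000032	HDL	T	0.034065	0.544	chr13	53200000	A	T
rs9000033	HDL	T	0.040434	0.797	chr13	53300000	T	G
rs9000034	HDL	A	0.047432	0.193	chr20	53400000	C	A
rs9000035	HDL	G	0.010496	0.449	chr15	53500000	G	C
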