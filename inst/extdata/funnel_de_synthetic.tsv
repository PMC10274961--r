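mirna_id	log2fc	p_value	q_value	call
miR-up-01	2.276	0.00296	0.02368	up
miR-up-02	2.128	0.00083	0.01044	up
miR-up-03	1.761	0.00087	0.01044	up
miR-up-04	2.929	0.01406	0.03367	up
miR-up-05	1.649	0.01164	0.03112	up
miR-up-06	3.034	0.01543	0.03367	up
miR-up-07	3.347	0.01014	0.03112	up
miR-up-08	2.211	0.02183	0.03832	up
miR-up-09	2.003	0.02395	0.03832	up
miR-up-10	2.717	0.02376	0.03832	up
miR-up-11	2.44	0.00929	0.03112	up
miR-up-12	2.185	0.02679	0.04018	up
miR-up-13	1.378	0.01933	0.03832	up
miR-up-14	2.513	0.01167	0.03112	up
miR-up-15	1.588	0.00475	0.02678	up
miR-dn-01	-1.6	0.00558	0.02678	down
miR-ns-01	-0.36	0.56565	0.64646	not_de
miR-ns-02	-0.236	0.29258	0.41305	not_de
miR-ns-03	0.584	0.77797	0.78777	not_de
miR-ns-04	-0.477	0.36824	0.46515	not_de
miR-ns-05	-0.33	0.35979	0.46515	not_de
miR-ns-06	-0.303	0.78777	0.78777	not_de
miR-ns-07	-0.162	0.51886	0.62263	not_de
miR-ns-08	0.303	0.63098	0.68834	not_de
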