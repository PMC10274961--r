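gene_id	supporting_mirnas	n_mirnas
ADH01	miR-up-01	1
ADH02	miR-up-02,miR-up-07	2
ADH03	miR-up-03	1
ADH04	miR-up-04,miR-up-05,miR-up-10	3
ADH05	miR-up-05	1
ADH06	miR-up-06,miR-up-13	2
ADH07	miR-up-07,miR-up-14	2
ADH08	miR-up-08	1
ADH09	miR-up-09	1
ADH10	miR-up-10	1
ADH11	miR-up-01,miR-up-11	2
ADH12	miR-up-12	1
ADH13	miR-up-13	1
ADH14	miR-up-14	1
ADH15	miR-up-15	1
ADH16	miR-up-01,miR-up-06	2
ADH17	miR-up-02,miR-up-11	2
ADH18	miR-up-03,miR-up-09,miR-up-15	3
ADH19	miR-up-04,miR-up-08	2
ADH20	miR-up-05,miR-up-12	2
ADH21	miR-up-06	1
ADH22	miR-up-07	1
ADH23	miR-up-08	1
ADH24	miR-up-09	1
ADH25	miR-up-03,miR-up-10	2
ADH26	miR-up-04,miR-up-11	2
ADH27	miR-up-12	1
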