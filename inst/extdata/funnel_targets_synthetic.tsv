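mirna_id	gene_id	database	evidence
miR-dn-01	DEC02	db_a	strong
miR-dn-01	DEC03	db_a	strong
miR-dn-01	DEC11	db_a	strong
miR-dn-01	DEC24	db_a	strong
miR-dn-01	DEC26	db_a	strong
miR-ns-01	DEC04	db_a	weak
miR-ns-01	DEC14	db_a	weak
miR-ns-01	DEC34	db_b	weak
miR-ns-01	DEC35	db_b	weak
miR-ns-02	DEC05	db_a	weak
miR-ns-02	DEC08	db_a	weak
miR-ns-02	DEC20	db_a	weak
miR-ns-02	DEC38	db_a	weak
miR-ns-03	DEC21	db_a	weak
miR-ns-03	DEC33	db_a	strong
miR-ns-03	DEC07	db_b	weak
miR-ns-03	DEC13	db_b	weak
miR-ns-04	DEC02	db_a	strong
miR-ns-04	DEC37	db_a	strong
miR-ns-04	DEC40	db_a	weak
miR-ns-04	DEC01	db_b	weak
miR-ns-05	DEC03	db_a	strong
miR-ns-05	DEC14	db_a	strong
miR-ns-05	DEC30	db_a	strong
miR-ns-05	DEC38	db_b	weak
miR-ns-06	DEC20	db_a	weak
miR-ns-06	DEC29	db_a	weak
miR-ns-06	DEC09	db_b	strong
miR-ns-06	DEC27	db_b	weak
miR-ns-07	DEC26	db_a	weak
miR-ns-07	DEC33	db_a	strong
miR-ns-07	DEC35	db_a	weak
miR-ns-07	DEC39	db_b	strong
miR-ns-08	DEC09	db_a	weak
miR-ns-08	DEC17	db_a	weak
miR-ns-08	DEC11	db_b	weak
miR-ns-08	DEC30	db_b	weak
miR-up-01	ADH01	db_a	strong
miR-up-01	ADH11	db_a	strong
miR-up-01	ADH16	db_a	strong
miR-up-01	DEC12	db_a	strong
miR-up-01	DEC21	db_a	weak
miR-up-01	DEC25	db_a	weak
miR-up-01	ADH01	db_b	strong
miR-up-01	ADH11	db_b	strong
miR-up-01	ADH16	db_b	strong
miR-up-01	DEC15	db_b	strong
miR-up-01	DEC23	db_b	weak
miR-up-01	DEC25	db_b	weak
miR-up-02	ADH02	db_a	strong
miR-up-02	ADH17	db_a	strong
miR-up-02	DEC14	db_a	strong
miR-up-02	DEC18	db_a	strong
miR-up-02	DEC20	db_a	weak
miR-up-02	ADH02	db_b	strong
miR-up-02	ADH17	db_b	strong
miR-up-02	DEC13	db_b	weak
miR-up-02	DEC37	db_b	weak
miR-up-02	DEC38	db_b	strong
miR-up-03	ADH03	db_a	strong
miR-up-03	ADH18	db_a	strong
miR-up-03	ADH25	db_a	strong
miR-up-03	DEC03	db_a	weak
miR-up-03	DEC08	db_a	strong
miR-up-03	DEC34	db_a	strong
miR-up-03	ADH03	db_b	strong
miR-up-03	ADH18	db_b	strong
miR-up-03	ADH25	db_b	strong
miR-up-03	DEC05	db_b	strong
miR-up-03	DEC18	db_b	weak
miR-up-03	DEC35	db_b	strong
miR-up-04	ADH04	db_a	strong
miR-up-04	ADH19	db_a	strong
miR-up-04	ADH26	db_a	strong
miR-up-04	DEC05	db_a	weak
miR-up-04	DEC30	db_a	strong
miR-up-04	DEC40	db_a	weak
miR-up-04	ADH04	db_b	strong
miR-up-04	ADH19	db_b	strong
miR-up-04	ADH26	db_b	strong
miR-up-04	DEC03	db_b	strong
miR-up-04	DEC21	db_b	strong
miR-up-04	DEC31	db_b	strong
miR-up-05	ADH04	db_a	strong
miR-up-05	ADH05	db_a	strong
miR-up-05	ADH20	db_a	strong
miR-up-05	DEC02	db_a	weak
miR-up-05	DEC08	db_a	strong
miR-up-05	DEC17	db_a	strong
miR-up-05	ADH04	db_b	strong
miR-up-05	ADH05	db_b	strong
miR-up-05	ADH20	db_b	strong
miR-up-05	DEC03	db_b	strong
miR-up-05	DEC04	db_b	weak
miR-up-05	DEC09	db_b	weak
miR-up-06	ADH06	db_a	strong
miR-up-06	ADH16	db_a	strong
miR-up-06	ADH21	db_a	strong
miR-up-06	DEC09	db_a	weak
miR-up-06	DEC15	db_a	weak
miR-up-06	DEC26	db_a	strong
miR-up-06	ADH06	db_b	strong
miR-up-06	ADH16	db_b	strong
miR-up-06	ADH21	db_b	strong
miR-up-06	DEC14	db_b	weak
miR-up-06	DEC20	db_b	strong
miR-up-06	DEC24	db_b	strong
miR-up-07	ADH02	db_a	strong
miR-up-07	ADH07	db_a	strong
miR-up-07	ADH22	db_a	strong
miR-up-07	DEC15	db_a	weak
miR-up-07	DEC30	db_a	strong
miR-up-07	DEC32	db_a	weak
miR-up-07	ADH02	db_b	strong
miR-up-07	ADH07	db_b	strong
miR-up-07	ADH22	db_b	strong
miR-up-07	DEC09	db_b	weak
miR-up-07	DEC24	db_b	strong
miR-up-07	DEC28	db_b	strong
miR-up-08	ADH08	db_a	strong
miR-up-08	ADH19	db_a	strong
miR-up-08	ADH23	db_a	strong
miR-up-08	DEC10	db_a	weak
miR-up-08	DEC26	db_a	strong
miR-up-08	DEC35	db_a	strong
miR-up-08	ADH08	db_b	strong
miR-up-08	ADH19	db_b	strong
miR-up-08	ADH23	db_b	strong
miR-up-08	DEC25	db_b	strong
miR-up-08	DEC38	db_b	weak
miR-up-08	DEC40	db_b	weak
miR-up-09	ADH09	db_a	strong
miR-up-09	ADH18	db_a	strong
miR-up-09	ADH24	db_a	strong
miR-up-09	DEC02	db_a	weak
miR-up-09	DEC13	db_a	weak
miR-up-09	DEC29	db_a	weak
miR-up-09	ADH09	db_b	strong
miR-up-09	ADH18	db_b	strong
miR-up-09	ADH24	db_b	strong
miR-up-09	DEC13	db_b	weak
miR-up-09	DEC36	db_b	weak
miR-up-09	DEC38	db_b	weak
miR-up-10	ADH04	db_a	strong
miR-up-10	ADH10	db_a	strong
miR-up-10	ADH25	db_a	strong
miR-up-10	DEC01	db_a	weak
miR-up-10	DEC16	db_a	strong
miR-up-10	DEC27	db_a	weak
miR-up-10	ADH04	db_b	strong
miR-up-10	ADH10	db_b	strong
miR-up-10	ADH25	db_b	strong
miR-up-10	DEC05	db_b	strong
miR-up-10	DEC09	db_b	strong
miR-up-10	DEC27	db_b	weak
miR-up-11	ADH11	db_a	strong
miR-up-11	ADH17	db_a	strong
miR-up-11	ADH26	db_a	strong
miR-up-11	DEC04	db_a	weak
miR-up-11	DEC05	db_a	strong
miR-up-11	DEC33	db_a	strong
miR-up-11	ADH11	db_b	strong
miR-up-11	ADH17	db_b	strong
miR-up-11	ADH26	db_b	strong
miR-up-11	DEC36	db_b	weak
miR-up-11	DEC37	db_b	strong
miR-up-11	DEC39	db_b	strong
miR-up-12	ADH12	db_a	strong
miR-up-12	ADH20	db_a	strong
miR-up-12	ADH27	db_a	strong
miR-up-12	DEC04	db_a	strong
miR-up-12	DEC09	db_a	weak
miR-up-12	DEC24	db_a	strong
miR-up-12	ADH12	db_b	strong
miR-up-12	ADH20	db_b	strong
miR-up-12	ADH27	db_b	strong
miR-up-12	DEC03	db_b	strong
miR-up-12	DEC07	db_b	weak
miR-up-12	DEC08	db_b	weak
miR-up-13	ADH06	db_a	strong
miR-up-13	ADH13	db_a	strong
miR-up-13	DEC03	db_a	weak
miR-up-13	DEC04	db_a	strong
miR-up-13	DEC08	db_a	strong
miR-up-13	ADH06	db_b	strong
miR-up-13	ADH13	db_b	strong
miR-up-13	DEC12	db_b	weak
miR-up-13	DEC16	db_b	strong
miR-up-13	DEC38	db_b	weak
miR-up-14	ADH07	db_a	strong
miR-up-14	ADH14	db_a	strong
miR-up-14	DEC12	db_a	weak
miR-up-14	DEC14	db_a	weak
miR-up-14	DEC27	db_a	strong
miR-up-14	ADH07	db_b	strong
miR-up-14	ADH14	db_b	strong
miR-up-14	DEC06	db_b	weak
miR-up-14	DEC18	db_b	strong
miR-up-14	DEC21	db_b	weak
miR-up-15	ADH15	db_a	strong
miR-up-15	ADH18	db_a	strong
miR-up-15	DEC01	db_a	strong
miR-up-15	DEC04	db_a	weak
miR-up-15	DEC20	db_a	weak
miR-up-15	ADH15	db_b	strong
miR-up-15	ADH18	db_b	strong
miR-up-15	DEC04	db_b	weak
miR-up-15	DEC13	db_b	weak
miR-up-15	DEC14	db_b	weak
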