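peptide	sequence	n_cys	pyroglu	predicted_native	measured_native	predicted_ra	measured_ra	exclude_from_reproduction
U-Asilidin_12_-Dg3a	ITCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR	6	FALSE	4057.97	4057.87	4328.15	4328.04	FALSE
U-Asilidin_12_-Dg3b	ITCDLIGNERLCVVHCLAKGFRGGWCDSRKVCNCRR	6	FALSE	4073.97	4073.85	4344.15	4344.03	FALSE
U-Asilidin_14_-Dg4	YDDHDPCFLKCKFWRSISRICVKTEDGTEKTLINESVLLCAKGCNRNWTLLHHGACPSDPGG	6	FALSE	6970.31	6970.17	7240.49	7241.37	FALSE
U-Asilidin_1_-Dg10a	KNDRECKKIAEVCYRHEECCSFQCPSYWGKCVS	6	FALSE	3921.70	3921.57	4191.88	4191.77	FALSE
U-Asilidin_1_-Dg10b	DRECKKIAEVCYRHEECCSFQCPSYWGKCVS	6	FALSE	3679.56	3679.45	3949.74	3949.64	FALSE
U-Asilidin_1_-Dg12	SQEQRQCKKIGEHCYVADECCSKRCLFYAAKCVS	6	FALSE	3906.76	3906.64	4176.94	4176.83	FALSE
U-Asilidin_15_-Dg14a	RECPTVENEKDIAVHLPHKDCSKYYACVKGKKIERKCPRGLLFNKTLQVCDFPERVKC	6	FALSE	6755.44	6755.28	7025.62	7026.48	FALSE
Kazal-Dg21-domain-2	SDFCPEVCPLLYKPVCGSYGDIKKIFPNECELKRANCKFGEAWEKINMDICRNIS	6	FALSE	6307.00	6306.90	6577.18	6577.09	FALSE
U-Asilidin_1_-Dg27	QDCNPEGARCSSDSDCCYSECIGSLCQP	6	TRUE	2946.03	2945.94	3216.21	NA	FALSE
U-Asilidin_1_-Dg28	RCVPRGGYCFNGSTLKCCRGVTTCINNRCR	6	FALSE	3330.54	3330.42	3600.72	3601.63	FALSE
U-Asilidin_1_-Dg29	SFRCSERGEPCFLRTTLNCCSGVSACIKNQCRF	6	FALSE	3708.67	3709.56	3978.85	3978.74	TRUE
Kazal-Dg51-domain-4	DFQKKCKLICPALYAPVCGFNGETYKWFQNKCIMEMDNCLFNHNWVADKMENCKA	6	FALSE	6472.94	6473.80	6743.12	6742.94	FALSE
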