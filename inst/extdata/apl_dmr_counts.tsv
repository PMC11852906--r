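comparison	n_dmrs	n_hyper	n_hypo
SSL_vs_SSL_NAT	6317	1271	5046
TA_vs_TA_NAT	36297	861	35436
VA_TVA_vs_VA_TVA_NAT	65794	1807	63987
SSL_vs_TA	1299	137	1162
SSL_vs_VA_TVA	11955	2096	9859
TA_vs_VA_TVA	651	91	560
SSL_NAT_vs_TA_NAT	4	NA	NA
SSL_NAT_vs_VA_TVA_NAT	30	NA	NA
TA_NAT_vs_VA_TVA_NAT	1	NA	NA
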