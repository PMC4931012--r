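strain_id	species	growth	GH29	GH95	SBP
BR-06	B. breve	grower	0	1	1
BR-10	B. breve	grower	0	1	1
BR-14	B. breve	grower	0	1	1
BR-15	B. breve	grower	0	1	1
BR-20	B. breve	grower	0	1	1
BR-21	B. breve	grower	0	1	1
BR-A29	B. breve	grower	0	1	1
BR-I29	B. breve	grower	0	1	1
BR-07	B. breve	non_grower	0	1	0
BR-19	B. breve	non_grower	0	1	0
BR-C29	B. breve	non_grower	0	1	0
BR-H29	B. breve	non_grower	0	1	0
BR-L29	B. breve	non_grower	0	1	0
IN-07	B. longum ss. infantis	grower	1	1	1
IN-F29	B. longum ss. infantis	grower	1	1	1
LO-06	B. longum ss. longum	non_grower	0	0	0
LO-10	B. longum ss. longum	non_grower	0	0	0
LO-21	B. longum ss. longum	non_grower	0	0	0
LO-C29	B. longum ss. longum	non_grower	0	0	0
LO-K29a	B. longum ss. longum	non_grower	0	0	0
LO-K29b	B. longum ss. longum	non_grower	0	0	0
CA-C29	B. pseudocatenulatum	grower	0	1	1
CA-K29a	B. pseudocatenulatum	grower	0	1	1
CA-K29b	B. pseudocatenulatum	grower	0	1	1
CA-05	B. pseudocatenulatum	non_grower	0	0	0
CA-B29	B. pseudocatenulatum	non_grower	0	0	0
CA-D29	B. pseudocatenulatum	non_grower	0	0	0
BI-14	B. bifidum	grower	1	1	0
DE-29	B. dentium	non_grower	1	0	0
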