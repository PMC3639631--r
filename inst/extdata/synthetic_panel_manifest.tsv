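gene	mrna_id	cds_start	cds_end
gene01	gene01_mrna	442	2573
gene02	gene02_mrna	539	2698
gene03	gene03_mrna	539	2471
gene04	gene04_mrna	599	2324
gene05	gene05_mrna	504	2359
gene06	gene06_mrna	599	2342
gene07	gene07_mrna	780	2419
gene08	gene08_mrna	852	2311
gene09	gene09_mrna	907	2241
gene10	gene10_mrna	617	1686
gene11	gene11_mrna	1092	2280
gene12	gene12_mrna	912	1860
gene13	gene13_mrna	1325	2300
gene14	gene14_mrna	676	2387
gene15	gene15_mrna	891	2033
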