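gene	planted_group	fd_mrna_target	fd_cds_target	fd_mrna_achieved	fd_cds_achieved	len_ratio
gene01	collinear	2.02	2.0227470923785154	2.020540003839875	2.023557662871332	0.6904145077720207
gene02	collinear	2.0233333333333334	2.0283672866484443	2.0226844469021374	2.0273065107716586	0.6689377516258904
gene03	collinear	2.026666666666667	2.03032874277518	2.0269149594826126	2.0326941169117525	0.6504037685060565
gene04	collinear	2.0300000000000002	2.039190561604276	2.0298649491346006	2.0393086503277975	0.6111898016997167
gene05	collinear	2.033333333333333	2.0406590155436306	2.0317844444617883	2.0414385535242623	0.5854889589905363
gene06	collinear	2.0366666666666666	2.042359063231764	2.0341550818529126	2.0443725096265397	0.5304136253041363
gene07	collinear	2.04	2.048974858104857	2.0408164092330785	2.0511036234363935	0.4998476074367571
gene08	collinear	2.0433333333333334	2.0534766494102583	2.0458034024529805	2.053970943364961	0.46526449968132566
gene09	collinear	2.046666666666667	2.0571515627033072	2.0450551221560156	2.0552004111972524	0.4494949494949495
gene10	collinear	2.05	2.0593892232256867	2.048197337729068	2.059036731928724	0.38894947291893855
gene11	collinear	2.0533333333333332	2.0670235623369018	2.0549809411779	2.0644429371175796	0.36316432498472817
gene12	collinear	2.0566666666666666	2.0687796864728227	2.054649638645146	2.0689139178288016	0.32071645826292666
gene13	collinear	2.06	2.0707575188389167	2.058460876346063	2.070975978543424	0.30433426878702835
gene14	offline	2.033333333333333	2.0233333333333334	2.0338230590611235	2.0257083504670508	0.5554834523036989
gene15	offline	2.046666666666667	2.036666666666667	2.0486394674604833	2.039067142390327	0.420839469808542
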