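cohort,case,original,nnunet,nnunet_resnet,ours,ratio_nnunet,ratio_nnunet_resnet,ratio_ours
dementia,1,29836,25752,29534,29474,0.8631,0.9898,0.9879
dementia,2,11298.1,8600,9018,9138,0.7611,0.7981,0.8088
dementia,3,31893.6,1452.1,5728.4,29711,0.0455,0.1796,0.9316
dementia,4,32734,2088,1902,4108,0.0637,0.0581,0.1255
dementia,5,55380,7993.6,3022.6,53673,0.1443,0.0545,0.9692
dementia,6,54510,1832,1834,4108,0.0336,0.0336,0.0754
dementia,7,68029.6,27628.7,27946.7,34154,0.4061,0.4108,0.5020
dementia,8,28806.4,1500.1,1372.1,25422,0.0520,0.0476,0.8825
dementia,9,18753,32543.8,30587.7,18160,-0.7353,-0.6310,0.9684
dementia,10,9592,18328,17842,3014,-0.9107,-0.8600,0.3142
dementia,11,48481.4,700,564,7286,0.0144,0.0116,0.1503
dementia,12,42134,24284.6,13850.6,26770,0.5763,0.3287,0.6354
dementia,13,26460,716,14,1694,0.0270,0.0005,0.0640
dementia,14,3329.6,4536,4244,1836,-0.3623,-0.2746,0.5514
dementia,15,20715.2,25690,26182,15796,-0.2401,-0.2639,0.7625
dementia,16,43534.4,8674,9068,29011.5,0.1992,0.2082,0.6664
dementia,17,4294,764.2,0,3704,0.1779,0,0.8626
dementia,18,4124,6052,14948,2430,-0.4675,-0.6246,0.5892
dementia,19,35618,670,552,27478,0.0188,0.0155,0.7715
dementia,20,22394,56541.6,55677.5,18160,0.7386,-0.4862,0.8109
MCI,1,14214,9728,440,13958,0.6843,0.0309,0.9820
MCI,2,12562,4436,376,9954,0.3531,0.0299,0.7924
MCI,3,17130,6818,1064,15122,0.3980,0.0621,0.8828
MCI,4,12924,6442,804,12404,0.4984,0.0622,0.9598
MCI,5,17508,5866,1290,14958,0.3350,0.0736,0.8544
MCI,6,13938,4956,370,7440,0.3555,0.0265,0.5338
MCI,7,18816,4968,4450,13670,0.2640,0.23655,0.7265
MCI,8,10890,15790,4,9326,-0.4499,0.0004,0.8564
MCI,9,13098,9956,1376,11880,0.7601,0.1051,0.9070
MCI,10,9105.2,10314,1070,7668,-0.1327,0.1175,0.8422
MCI,11,12898,17592,168,7966,-0.3639,0.0130,0.6176
MCI,12,9948,8222.9,0,9638,0.8265,0,0.9688
MCI,13,17863,9962,116,15678,0.5576,0.0065,0.8777
MCI,14,12530.7,10130,796,10700,0.8084,0.0635,0.8539
MCI,15,15440,18420,2076,12826,-0.1930,0.1345,0.8307
MCI,16,14580,4648.8,1038,5630,0.3188,0.0712,0.3861
MCI,17,15232,9068.8,188,12634,0.5953,0.0123,0.8294
MCI,18,10056,15858,1212,7599,-0.5769,0.1205,0.7557
MCI,19,9858,5000,3864,5194,0.5072,0.3920,0.5269
MCI,20,16501,8704,1440,16160,0.5274,0.0873,0.9793
NCI,1,2358,4046,9460,2108,-0.7158,-0.0119,0.8940
NCI,2,1806,624.1,4732,794,0.3455,-0.6202,0.4396
NCI,3,1790,990,12142,1598,0.5530,-0.7832,0.8927
NCI,4,5615.4,676,10722,4046,0.1203,-0.9094,0.7205
NCI,5,2994,3150,9976,2642,-0.0521,-0.3320,0.8824
NCI,6,2778,2322,13366,1966,0.8358,-0.8114,0.7077
NCI,7,2630.2,170,14418,566,0.0646,-0.4817,0.2152
NCI,8,5560,3810,622,4692,0.6852,0.1119,0.8439
NCI,9,4056,574,32594,3116,0.1415,-0.0360,0.7682
NCI,10,4118,2606.2,11934.8,2812,0.6328,-0.8982,0.6829
NCI,11,6338,2732,32712,4305,0.4310,-0.1612,0.6792
NCI,12,1934,1144,624.2,1058,0.5915,0.3228,0.5471
NCI,13,1448,539.9,14170,468,0.3728,-0.7859,0.3232
NCI,14,1716,236,42,348,0.1375,0.02448,0.2028
NCI,15,3064,240,33756,2750,0.7859,-0.0170,0.8975
NCI,16,5426,1074,6189,4310,0.1979,-0.1406,0.7943
NCI,17,3009.4,202,8694.8,2262,0.0671,-0.8892,0.7516
NCI,18,3958,1434,14660,2292,0.3623,-0.7039,0.5791
NCI,19,2216,3328,4870,370,-0.5018,-0.1977,0.1670
NCI,20,1962,1366,10180,1706,0.6962,-0.1889,0.8695
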