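"age","sex","stage","ps","smoking","comorbidity","location3","histology","wbc","neut","lymph","plt","nlr","sii","mld","v5","v20","v30","chemo","chemo_concurrent","immuno","rp_grade","event"
71.2059,1,4,2,"never",1,1,1,3.1111,1.8081,0.703,178.5488,2.5721,459.2394,12.0461,44.7816,24.1532,15.3596,1,1,0,0,0
59.9719,1,3,0,"former",1,3,3,3.8203,2.4838,0.7365,387.7505,3.3727,1307.7644,5.3157,20.0516,8.1503,13.6106,1,1,1,0,0
67.588,2,4,0,"former",0,1,3,2.7481,1.5247,0.6234,197.6011,2.4459,483.3098,10.4193,46.2324,18.658,37.5087,0,0,0,2,1
60.1902,1,3,1,"former",1,3,2,2.8665,1.5703,0.6962,90.0585,2.2553,203.1126,9.4671,33.9099,15.0498,8.4089,1,1,1,0,0
51.7934,1,4,1,"never",1,1,1,2.193,0.619,0.974,3002.5579,0.6356,1908.3245,7.0157,26.103,14.9493,7.4738,0,0,0,0,0
72.7181,1,4,1,"never",1,3,2,5.149,3.1673,1.3818,3490.043,2.2922,7999.9266,0.7612,8.9349,4.853,2.6718,1,1,0,2,1
61.3604,2,3,2,"former",1,1,1,1.9492,0.506,0.8432,84.6148,0.6,50.7727,6.7305,24.5426,8.8026,2.6395,0,0,0,0,0
49.5877,2,3,0,"former",1,1,1,9.9088,8.2755,1.0333,336.3119,8.0085,2693.363,5.5574,19.1812,10.8136,3.4924,1,0,0,0,0
54.1733,1,3,1,"former",1,3,2,2.8074,1.2074,1.0001,234.0816,1.2073,282.5973,10.31,40.7239,20.9735,7.9857,1,1,1,0,0
54.3613,2,4,1,"former",0,1,1,8.2843,5.9041,1.7802,459.3669,3.3166,1523.5252,7.8233,32.572,14.3947,7.0584,1,0,0,2,1
67.8119,1,4,1,"never",0,1,3,16.1218,12.7472,2.7747,12.9076,4.5941,59.2988,8.0992,28.5726,13.4046,6.677,1,1,1,0,0
66.0698,1,1,0,"former",0,1,1,3.4721,2.1405,0.7315,123.7567,2.926,362.1115,6.7501,25.4347,10.3587,10.6708,1,0,0,0,0
57.0129,2,4,1,"never",0,3,1,25.6223,22.6386,2.3837,16.997,9.4973,161.4257,8.8878,33.7236,20.1809,11.2803,1,0,0,0,0
65.6474,1,3,0,"never",0,1,1,6.8172,3.6101,2.6071,200.4733,1.3847,277.6026,8.8693,30.288,16.41,3.3251,1,1,0,0,0
61.1108,1,3,1,"never",1,3,3,7.0941,5.2682,1.2259,32.7532,4.2973,140.7505,0.7133,2.8222,4.3245,0.9908,1,1,1,2,1
74.1539,1,3,1,"former",0,2,2,4.1691,1.9724,1.5967,607.6686,1.2353,750.6576,15.5849,66.7685,28.1405,17.4958,1,0,1,2,1
51.1321,1,4,1,"never",1,1,1,11.6959,10.5352,0.5607,106.4304,18.7898,1999.8038,12.4557,51.4977,27.0088,6.4038,1,0,0,0,0
58.8225,1,3,1,"never",0,1,1,9.1202,7.1731,1.3471,51.9197,5.3249,276.4654,10.7529,38.4791,21.8854,20.1441,1,0,0,0,0
53.8716,1,4,0,"former",1,3,1,3.4421,1.9411,0.901,174.5846,2.1544,376.1298,6.442,26.2091,12.368,1.3964,0,0,1,0,0
47.2163,1,3,1,"never",0,2,1,7.7214,6.0742,1.0472,23.3201,5.8004,135.2657,12.7693,48.1726,27.2993,22.1187,1,1,0,0,0
64.7178,1,3,1,"never",1,2,1,3.4631,1.4707,1.3924,1467.0596,1.0563,1549.5925,8.4346,31.8187,15.191,3.1341,1,1,1,0,0
52.7701,2,3,1,"former",1,1,3,20.7374,18.4518,1.6855,85.6687,10.9472,937.8345,9.1282,38.6329,16.5264,22.7428,1,0,0,0,0
53.4928,1,4,1,"former",1,3,3,2.8578,1.1598,1.098,75.8466,1.0563,80.1192,4.0788,18.1271,7.7736,3.7245,1,1,0,0,0
70.9058,1,3,1,"former",1,3,1,6.1564,2.3681,3.1883,3657.7356,0.7428,2716.7973,16.0945,65.6728,30.4893,26.9979,1,1,1,2,1
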