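"depth_m","par_noon","din","po4","fe","cells_per_m3","mu_obs"
0,600,2.11527e-05,5.0289e-05,0.03,1.5139e+11,0.4388
5,479.11,2.16473e-05,5.03948e-05,0.03,1.4923e+11,NA
10,382.577,2.23538e-05,5.0539e-05,0.03,1.475e+11,NA
15,305.494,2.3363e-05,5.07358e-05,0.03,1.4635e+11,0.4288
20,243.942,2.48042e-05,5.10039e-05,0.03,1.4593e+11,NA
25,194.791,2.68616e-05,5.13688e-05,0.03,1.464e+11,NA
30,155.544,2.97972e-05,5.18647e-05,0.03,1.4793e+11,0.4109
35,124.205,3.39829e-05,5.25372e-05,0.03,1.5069e+11,NA
40,99.1793,3.99447e-05,5.34466e-05,0.03,1.5476e+11,NA
45,79.1963,4.84241e-05,5.46716e-05,0.03,1.6021e+11,0.382
50,63.2395,6.04592e-05,5.63132e-05,0.03,1.6696e+11,NA
55,50.4978,7.74909e-05,5.84979e-05,0.03,1.7483e+11,NA
60,40.3233,0.000101493,6.13787e-05,0.03,1.8353e+11,NA
65,32.1988,0.000135122,6.51318e-05,0.03,1.926e+11,NA
70,25.7113,0.000181854,6.99446e-05,0.03512,2.015e+11,NA
75,20.5309,0.000246057,7.59932e-05,0.04551,2.0961e+11,0.2942
80,16.3942,0.000332902,8.3405e-05,0.05866,2.163e+11,NA
85,13.0911,0.000447925,9.22108e-05,0.0751,2.2098e+11,NA
90,10.4534,0.000596098,0.000102297,0.09532,2.2318e+11,0.2504
95,8.34723,0.000780292,0.000113376,0.1198,2.2258e+11,NA
100,6.6654,0.000999385,0.000125,0.1486,2.1908e+11,NA
105,5.32243,0.00124672,0.000136624,0.1818,2.1278e+11,NA
110,4.25005,0.00151,0.000147703,0.2187,2.0399e+11,NA
115,3.39373,0.00177328,0.000157789,0.2586,1.9318e+11,NA
120,2.70995,0.00202062,0.000166595,0.3,1.8095e+11,0.1962
125,2.16394,0.00223971,0.000174007,0.3414,1.6792e+11,NA
130,1.72794,0.0024239,0.000180055,0.3813,1.5471e+11,NA
135,1.37979,0.00257208,0.000184868,0.4182,1.4187e+11,NA
140,1.10178,0.0026871,0.000188621,0.4514,1.2983e+11,NA
145,0.879791,0.00277394,0.000191502,0.4802,1.189e+11,NA
150,0.702528,0.00283815,0.000193687,0.5047,1.0926e+11,0.1772
155,0.56098,0.00288488,0.000195328,0.5249,1.0097e+11,NA
160,0.447951,0.00291851,0.000196553,0.5413,9.399e+10,NA
165,0.357697,0.00294251,0.000197463,0.5545,8.8201e+10,0.1737
170,0.285626,0.00295954,0.000198135,0.5649,8.3454e+10,NA
175,0.228077,0.00297158,0.000198631,0.573,7.9576e+10,NA
180,0.182123,0.00298006,0.000198996,0.5793,7.6399e+10,0.1719
185,0.145429,0.00298602,0.000199264,0.5842,7.3765e+10,NA
190,0.116127,0.0029902,0.000199461,0.588,7.1542e+10,NA
195,0.0927293,0.00299314,0.000199605,0.5908,6.9621e+10,NA
200,0.0740459,0.0029952,0.000199711,0.593,6.7918e+10,NA
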