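row,species,replicate_group,kt,d_kt,kr_np,d_kr_np,c_np,d_c_np,l_np,d_l_np,nh_calc_np,d_nh_calc_np,kr_ph,d_kr_ph,c_ph,d_c_ph,l_ph_1e5,d_l_ph_1e5,nh_calc_ph,d_nh_calc_ph,nh_obs,d_nh_obs
1,African elephant 1,elephant,102.3,2.7,18.2,0.1,0.178,0.005,1.6,0.2,1.18,0.01,0.5,0.1,0.005,0.001,30.2,3.2,2.85,0.20,2.84,0.07
2,African elephant 2,elephant,138.0,12.4,18.3,0.5,0.133,0.012,2.0,0.7,1.23,0.06,1.6,0.2,0.011,0.002,0.4,0.1,2.87,0.17,2.92,0.17
3,Asian elephant,elephant,63.1,2.4,19.4,0.1,0.308,0.012,1.1,0.2,1.18,0.05,0.3,0.2,0.003,0.001,240.3,92.5,2.88,0.80,3.01,0.16
4,Horse,,112.2,1.3,19.3,0.1,0.172,0.002,1.8,0.1,1.11,0.01,1.4,0.5,0.012,0.006,0.7,0.6,2.74,0.58,2.76,0.02
5,Camel,,72.4,1.1,19.3,0.2,0.266,0.005,2.0,0.1,1.20,0.01,2.6,0.1,0.036,0.001,0.1,0.1,2.20,0.02,2.26,0.05
6,Cow,,89.1,0.6,20.6,0.1,0.232,0.002,1.4,0.0,1.19,0.01,0.2,0.1,0.002,0.001,1565.4,9.7,2.67,0.27,2.87,0.05
7,Mole,,91.2,2.0,20.7,0.1,0.226,0.005,1.5,0.1,1.18,0.01,0.7,0.1,0.008,0.001,9.5,0.3,2.61,0.06,2.68,0.1
8,Orangutan,,120.2,8.4,21.4,0.3,0.178,0.013,1.6,0.4,1.15,0.01,0.7,0.2,0.006,0.002,16.6,6.2,2.84,0.48,2.76,0.09
9,Gorilla-F,,93.3,2.1,21.7,0.2,0.232,0.006,1.4,0.1,1.18,0.01,0.1,0.1,0.002,0.001,7457.4,86.7,2.68,0.78,2.72,0.16
10,Chimpanzee,,95.5,2.0,21.7,0.2,0.227,0.005,1.5,0.1,1.16,0.01,0.7,0.1,0.008,0.001,12,1.1,2.62,0.20,2.87,0.08
11,Platypus,,158.5,1.6,21.5,0.1,0.135,0.002,1.9,0.1,1.18,0.04,1.3,0.3,0.008,0.003,1.3,0.9,2.94,0.33,3.18,0.04
12,Human (Clerbaux et al),human,123.0,1.3,22.0,0.1,0.179,0.002,1.5,0.1,1.15,0.01,0.5,0.1,0.004,0.001,62.1,13.9,2.87,0.40,2.77,0.06
13,Human (Severinghaus et al),human,125.9,0.6,22.0,0.0,0.175,0.001,1.7,0.0,1.16,0.01,1.1,0.1,0.009,0.001,2.5,0.5,2.79,0.18,2.93,0.03
14,Human (Imai),human,128.8,0.8,22.1,0.1,0.171,0.001,1.8,0.0,1.22,0.01,1.6,0.1,0.013,0.001,0.7,0.1,2.74,0.04,2.91,0.02
15,Antelope,,338.8,37.0,23.0,0.3,0.068,0.007,1.9,0.8,1.18,0.01,0.5,0.5,0.002,0.002,83.4,142.8,3.46,0.80,3.59,0.15
16,Goat,,436.5,26.9,23.5,0.1,0.054,0.003,1.9,0.5,1.19,0.01,0.4,0.5,0.001,0.001,274.5,494.2,3.57,0.78,3.54,0.11
17,Dog,,104.7,1.0,23.7,0.1,0.226,0.002,1.5,0.1,1.20,0.01,0.8,0.1,0.008,0.001,9.2,0.1,2.61,0.07,2.62,0.06
18,Llama,,97.7,0.7,23.0,0.1,0.235,0.002,1.3,0.0,1.14,0.01,NA,NA,NA,NA,NA,NA,NA,NA,2.90,0.06
19,Yak,,338.8,37.0,23.0,0.3,0.068,0.007,1.9,0.8,1.23,0.08,NA,NA,NA,NA,NA,NA,NA,NA,3.59,0.15
20,Gorilla-M,,144.5,1.9,21.0,0.1,0.145,0.002,1.4,0.1,1.24,0.05,NA,NA,NA,NA,NA,NA,NA,NA,3.54,0.11
21,Echidna,,97.7,0.7,23.0,0.1,0.235,0.002,1.3,0.0,1.16,0.01,NA,NA,NA,NA,NA,NA,NA,NA,2.62,0.06
22,Deer,,131.8,2.2,24.1,0.1,0.183,0.003,1.4,0.1,1.17,0.01,NA,NA,NA,NA,NA,NA,NA,NA,2.99,0.07
23,Shrew,,239.9,2.4,27.7,0.0,0.115,0.001,1.4,0.1,1.18,0.01,NA,NA,NA,NA,NA,NA,NA,NA,3.30,0.06
24,Hedgehog,,208.9,1.8,30.6,0.0,0.146,0.001,1.4,0.0,1.17,0.01,NA,NA,NA,NA,NA,NA,NA,NA,3.15,0.04
25,Ringtailed lemur,,213.8,13.7,30.9,0.2,0.144,0.009,1.4,0.4,1.18,0.04,NA,NA,NA,NA,NA,NA,NA,NA,3.29,0.19
26,Brown galago,,131.8,5.5,30.8,0.3,0.234,0.001,1.3,0.2,1.15,0.02,NA,NA,NA,NA,NA,NA,NA,NA,2.91,0.14
27,Black galago,,166.0,9.3,31.4,0.2,0.189,0.011,1.2,0.3,1.15,0.03,NA,NA,NA,NA,NA,NA,NA,NA,2.94,0.14
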