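n,En_H,Es_GA2,En_GA2,En_DD,Es_ABC2
2,42.4156,77.6273,41.0904,217.4252,37.7476
3,60.9452,109.6806,58.1305,321.2256,52.1344
4,74.0452,130.5868,69.7692,397.3709,62.2993
5,92.5372,163.3578,87.0582,500.9904,76.2604
6,105.5011,188.1582,99.8468,576.5361,85.7444
7,123.9716,221.5539,117.2291,680.0174,99.4414
8,137.1272,246.5397,130.2352,756.5490,108.8549
9,155.5456,282.0612,148.2364,859.7601,122.3128
10,168.6165,308.3171,161.5894,935.8338,131.6698
11,187.1002,345.4395,180.2012,1039.4182,145.0638
12,200.1333,372.0528,193.6316,1115.2485,154.3475
13,218.6333,409.2243,212.2461,1218.8922,167.7026
14,231.6943,436.5013,225.9625,1294.9403,176.9359
15,250.1350,474.6518,244.8417,1398.2733,190.2373
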