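region,year,gap,ratio
Shandong,2011,-0.150,0.281
Shandong,2012,-0.226,0.333
Shandong,2013,-0.037,0.704
Shandong,2014,0.032,1.087
Shandong,2015,0.027,1.064
Shandong,2016,0.028,1.052
Shandong,2017,0.025,1.043
Shandong,2018,0.143,1.237
Shandong,2019,0.180,1.286
Shandong,2020,0.185,1.259
Jiangsu,2011,-0.122,0.382
Jiangsu,2012,-0.162,0.414
Jiangsu,2013,-0.104,0.664
Jiangsu,2014,0.011,1.033
Jiangsu,2015,0.039,1.112
Jiangsu,2016,0.070,1.163
Jiangsu,2017,0.070,1.125
Jiangsu,2018,0.058,1.093
Jiangsu,2019,0.077,1.114
Jiangsu,2020,0.152,1.207
Zhejiang,2011,-0.194,0.299
Zhejiang,2012,-0.132,0.447
Zhejiang,2013,-0.141,0.467
Zhejiang,2014,-0.088,0.806
Zhejiang,2015,0.000,0.999
Zhejiang,2016,0.013,1.031
Zhejiang,2017,0.101,1.221
Zhejiang,2018,0.136,1.242
Zhejiang,2019,0.104,1.151
Zhejiang,2020,0.118,1.160
Fujian,2011,-0.147,0.428
Fujian,2012,-0.189,0.461
Fujian,2013,-0.129,0.692
Fujian,2014,-0.001,0.997
Fujian,2015,-0.010,0.979
Fujian,2016,0.063,1.123
Fujian,2017,0.109,1.198
Fujian,2018,0.154,1.249
Fujian,2019,0.177,1.270
Fujian,2020,0.173,1.241
Guangdong,2011,-0.176,0.382
Guangdong,2012,-0.112,0.606
Guangdong,2013,-0.104,0.737
Guangdong,2014,-0.008,0.983
Guangdong,2015,0.043,1.081
Guangdong,2016,0.100,1.184
Guangdong,2017,0.124,1.208
Guangdong,2018,0.159,1.257
Guangdong,2019,0.195,1.308
Guangdong,2020,0.215,1.319
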