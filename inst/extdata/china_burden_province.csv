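province,an_2000_2021,an_2022,af_2000_2021,af_2022
Xizang,48,121,6.04,15.69
Sichuan,1505,3620,6.19,14.46
Chongqing,604,1351,6.52,14.35
Guizhou,671,1376,8.58,18.54
Zhejiang,1771,3941,15.40,33.19
Hunan,1726,3933,10.02,21.47
Qinghai,59,130,5.88,12.37
Jiangxi,952,2057,10.29,20.51
Jiangsu,3009,5753,15.33,30.40
Henan,2948,6094,12.34,24.38
Hubei,1590,3371,10.36,20.41
Anhui,2521,4977,16.43,31.59
Fujian,703,1262,10.00,19.07
Shanghai,735,1660,14.59,27.77
Gansu,360,681,6.22,11.27
Xinjiang,267,420,6.65,10.45
Shaanxi,641,1085,7.07,10.98
Ningxia,75,106,6.89,10.14
Guangdong,1508,2016,9.36,13.71
Shandong,4107,6425,16.75,23.10
Beijing,395,662,11.08,15.23
Guangxi,950,1322,9.33,12.61
Shanxi,973,1386,11.85,15.50
Hebei,2362,3594,11.58,14.85
Tianjin,375,557,11.23,14.25
Yunnan,494,631,4.78,5.67
Hainan,132,142,9.70,10.02
Inner Mongolia,758,847,11.09,11.31
Liaoning,1668,1627,11.10,9.66
Heilongjiang,1250,1214,10.65,8.83
Jilin,830,600,10.69,6.67
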