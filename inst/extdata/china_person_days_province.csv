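province,pd_0_64_2000_2021,pd_0_64_2022,pd_65p_2000_2021,pd_65p_2022
Sichuan,1505.49,3277.70,192.57,668.09
Henan,2153.06,4191.20,213.11,653.42
Jiangsu,1664.34,3322.33,212.72,642.12
Hunan,1452.84,3063.95,166.82,532.76
Zhejiang,1174.93,2855.96,137.03,436.87
Shandong,2190.34,3088.02,258.83,550.64
Anhui,1357.25,2480.75,155.34,438.08
Hubei,1309.79,2374.25,137.66,405.48
Jiangxi,1040.12,2188.26,95.37,295.18
Guangdong,2310.82,3902.44,181.09,366.30
Hebei,1525.11,2011.64,151.00,325.38
Shanghai,474.08,1160.93,65.00,225.75
Chongqing,565.57,1107.91,73.45,228.15
Fujian,832.11,1663.19,77.87,207.62
Shaanxi,820.12,1273.12,78.14,195.70
Guizhou,669.85,1380.04,63.83,180.32
Shanxi,792.06,1081.31,71.67,160.17
Gansu,499.89,883.25,42.94,127.12
Guangxi,954.31,1306.26,100.65,181.46
Beijing,413.45,761.72,45.96,116.86
Liaoning,873.51,750.46,110.96,158.26
Tianjin,271.81,418.28,29.85,72.39
Yunnan,694.58,867.39,62.25,104.43
Heilongjiang,753.00,612.89,74.07,113.40
Xinjiang,476.03,858.47,33.21,72.21
Inner Mongolia,520.30,543.52,46.36,81.59
Qinghai,108.25,257.84,7.40,24.50
Ningxia,139.13,230.26,9.66,24.51
Xizang,61.66,184.20,3.63,11.08
Hainan,192.59,219.60,18.23,25.57
Jilin,534.37,321.15,54.75,59.39
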