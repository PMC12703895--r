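province,cedd_2000_2021,cedd_2022
Sichuan,781.76,3827.13
Henan,901.84,2396.54
Hubei,690.28,2178.60
Anhui,779.07,2130.34
Jiangsu,587.43,1701.55
Zhejiang,404.46,1471.22
Hunan,530.75,1545.07
Jiangxi,391.94,1240.47
Xinjiang,1133.60,1977.40
Guizhou,284.26,948.26
Gansu,669.43,1319.55
Shandong,766.82,1397.15
Qinghai,357.66,884.30
Shaanxi,471.56,941.44
Xizang,170.16,617.97
Guangdong,475.11,905.47
Fujian,241.84,662.43
Shanxi,514.87,892.32
Hebei,538.13,871.30
Guangxi,345.85,525.10
Ningxia,242.34,414.97
Yunnan,380.21,541.96
Chongqing,37.16,171.54
Shanghai,30.53,103.79
Tianjin,46.88,68.05
Inner Mongolia,683.44,702.89
Beijing,47.47,61.42
Liaoning,584.99,472.08
Hainan,379.91,244.15
Jilin,427.55,266.78
Heilongjiang,652.25,426.68
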