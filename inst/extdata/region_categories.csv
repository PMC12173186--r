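region,category
Beijing,eastern
Tianjin,eastern
Hebei,eastern
Liaoning,eastern
Shanghai,eastern
Jiangsu,eastern
Zhejiang,eastern
Fujian,eastern
Shandong,eastern
Guangdong,eastern
Guangxi,eastern
Hainan,eastern
Shanxi,central
Mongolia,central
Jilin,central
Heilongjiang,central
Anhui,central
Jiangxi,central
Henan,central
Hubei,central
Hunan,central
Chongqing,western
Sichuan,western
Guizhou,western
Yunnan,western
Tibet,western
Shaanxi,western
Gansu,western
Ningxia,western
Qinghai,western
Xinjiang,western
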