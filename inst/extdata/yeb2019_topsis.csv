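region_id,level,year,d_plus,d_minus,closeness,rank
Shanghai,province,2019,0.35733388,0.44132568,0.55258,1
Jiangsu,province,2019,0.40273532,0.36503935,0.47545,4
Zhejiang,province,2019,0.3416379,0.3829833,0.52853,2
Anhui,province,2019,0.56931864,0.08609698,0.13136,11
Jiangxi,province,2019,0.52905381,0.15980787,0.23199,10
Hubei,province,2019,0.49376154,0.20971995,0.29812,8
Hunan,province,2019,0.46564982,0.27007067,0.36708,7
Chongqing,province,2019,0.37722752,0.37095765,0.49581,3
Sichuan,province,2019,0.39893428,0.35542655,0.47116,5
Guizhou,province,2019,0.41864762,0.27516591,0.3966,6
Yunnan,province,2019,0.46866656,0.18797558,0.28627,9
Downstream,reach,2019,0.67955724,0.62286267,0.47823,1
Midstream,reach,2019,0.78144644,0.51599592,0.3977,3
Upstream,reach,2019,0.64884081,0.58714994,0.47504,2
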