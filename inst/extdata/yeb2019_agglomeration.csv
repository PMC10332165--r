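region_id,level,year,indicator,hrad,hrad_rank,pad,ratio,ratio_rank
Shanghai,province,2019,health_institutions,4.744,1,13.32,0.356,11
Jiangsu,province,2019,health_institutions,1.823,2,2.736,0.666,9
Zhejiang,province,2019,health_institutions,1.801,3,1.999,0.901,7
Anhui,province,2019,health_institutions,1.016,8,1.583,0.642,10
Jiangxi,province,2019,health_institutions,1.208,6,0.985,1.226,3
Hubei,province,2019,health_institutions,1.018,7,1.099,0.926,6
Hunan,province,2019,health_institutions,1.461,4,1.143,1.278,2
Chongqing,province,2019,health_institutions,1.374,5,1.319,1.042,5
Sichuan,province,2019,health_institutions,0.922,9,0.597,1.545,1
Guizhou,province,2019,health_institutions,0.881,10,0.724,1.216,4
Yunnan,province,2019,health_institutions,0.315,11,0.387,0.814,8
Downstream,reach,2019,health_institutions,1.547,1,2.253,0.687,3
Midstream,reach,2019,health_institutions,1.239,2,1.082,1.145,2
Upstream,reach,2019,health_institutions,0.723,3,0.589,1.229,1
Shanghai,province,2019,tcm_institutions,5.323,1,13.32,0.4,11
Jiangsu,province,2019,tcm_institutions,1.877,4,2.736,0.686,8
Zhejiang,province,2019,tcm_institutions,2.585,3,1.999,1.293,3
Anhui,province,2019,tcm_institutions,0.783,7,1.583,0.495,10
Jiangxi,province,2019,tcm_institutions,0.68,9,0.985,0.691,7
Hubei,province,2019,tcm_institutions,0.697,8,1.099,0.634,9
Hunan,province,2019,tcm_institutions,1.002,6,1.143,0.877,4
Chongqing,province,2019,tcm_institutions,2.964,2,1.319,2.247,1
Sichuan,province,2019,tcm_institutions,1.142,5,0.597,1.914,2
Guizhou,province,2019,tcm_institutions,0.586,10,0.724,0.81,6
Yunnan,province,2019,tcm_institutions,0.316,11,0.387,0.815,5
Downstream,reach,2019,tcm_institutions,1.708,1,2.253,0.758,2
Midstream,reach,2019,tcm_institutions,0.806,3,1.082,0.745,3
Upstream,reach,2019,tcm_institutions,0.882,2,0.589,1.498,1
Shanghai,province,2019,beds,12.162,1,13.32,0.913,8
Jiangsu,province,2019,beds,2.648,2,2.736,0.968,7
Zhejiang,province,2019,beds,1.811,3,1.999,0.906,9
Anhui,province,2019,beds,1.307,5,1.583,0.826,11
Jiangxi,province,2019,beds,0.853,8,0.985,0.867,10
Hubei,province,2019,beds,1.132,7,1.099,1.03,5
Hunan,province,2019,beds,1.266,6,1.143,1.108,3
Chongqing,province,2019,beds,1.482,4,1.319,1.123,2
Sichuan,province,2019,beds,0.682,10,0.597,1.142,1
Guizhou,province,2019,beds,0.802,9,0.724,1.107,4
Yunnan,province,2019,beds,0.376,11,0.387,0.972,6
Downstream,reach,2019,beds,2.042,1,2.253,0.906,3
Midstream,reach,2019,beds,1.385,2,1.082,1.28,1
Upstream,reach,2019,beds,0.61,3,0.589,1.036,2
Shanghai,province,2019,grassroots_beds,6.466,1,13.32,0.485,10
Jiangsu,province,2019,grassroots_beds,2.487,2,2.736,0.909,8
Zhejiang,province,2019,grassroots_beds,0.762,9,1.999,0.381,11
Anhui,province,2019,grassroots_beds,1.271,6,1.583,0.803,9
Jiangxi,province,2019,grassroots_beds,0.964,7,0.985,0.979,6
Hubei,province,2019,grassroots_beds,1.355,5,1.099,1.233,4
Hunan,province,2019,grassroots_beds,1.493,4,1.143,1.306,3
Chongqing,province,2019,grassroots_beds,1.752,3,1.319,1.328,1
Sichuan,province,2019,grassroots_beds,0.787,8,0.597,1.319,2
Guizhou,province,2019,grassroots_beds,0.751,10,0.724,1.037,5
Yunnan,province,2019,grassroots_beds,0.358,11,0.387,0.924,7
Downstream,reach,2019,grassroots_beds,1.573,1,2.253,0.698,3
Midstream,reach,2019,grassroots_beds,1.189,2,1.082,1.099,1
Upstream,reach,2019,grassroots_beds,0.566,3,0.589,0.962,2
Shanghai,province,2019,health_technicians,15.562,1,13.32,1.168,2
Jiangsu,province,2019,health_technicians,2.978,2,2.736,1.089,3
Zhejiang,province,2019,health_technicians,2.466,3,1.999,1.234,1
Anhui,province,2019,health_technicians,1.246,5,1.583,0.787,11
Jiangxi,province,2019,health_technicians,0.784,8,0.985,0.796,10
Hubei,province,2019,health_technicians,1.071,7,1.099,0.974,8
Hunan,province,2019,health_technicians,1.151,6,1.143,1.007,5
Chongqing,province,2019,health_technicians,1.316,4,1.319,0.998,7
Sichuan,province,2019,health_technicians,0.596,10,0.597,0.998,6
Guizhou,province,2019,health_technicians,0.742,9,0.724,1.025,4
Yunnan,province,2019,health_technicians,0.376,11,0.387,0.97,9
Downstream,reach,2019,health_technicians,2.366,1,2.253,1.05,3
Midstream,reach,2019,health_technicians,1.528,2,1.082,1.412,1
Upstream,reach,2019,health_technicians,0.64,3,0.589,1.087,2
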