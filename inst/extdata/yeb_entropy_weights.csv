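level,indicator,entropy,utility,weight
province,health_institutions,0.924,0.076,0.065
province,tcm_institutions,0.824,0.176,0.152
province,beds,0.9,0.1,0.086
province,grassroots_beds,0.921,0.079,0.068
province,health_technicians,0.902,0.098,0.084
province,physicians,0.891,0.109,0.094
province,nurses,0.909,0.091,0.078
province,primary_health_technicians,0.932,0.068,0.059
province,general_practitioners,0.826,0.174,0.15
province,gov_health_expenditure,0.81,0.19,0.164
reach,health_institutions,0.629,0.371,0.063
reach,tcm_institutions,0.081,0.919,0.157
reach,beds,0.522,0.478,0.082
reach,grassroots_beds,0.613,0.387,0.066
reach,health_technicians,0.283,0.717,0.122
reach,physicians,0.222,0.778,0.133
reach,nurses,0.617,0.383,0.065
reach,primary_health_technicians,0.514,0.486,0.083
reach,general_practitioners,0.028,0.972,0.166
reach,gov_health_expenditure,0.631,0.369,0.064
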