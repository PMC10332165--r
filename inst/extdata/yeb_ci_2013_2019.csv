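year,health_institutions,tcm_institutions,beds,grassroots_beds,health_technicians,physicians,nurses,primary_health_technicians,general_practitioners,gov_health_expenditure
2019,-0.119,-0.056,-0.018,-0.073,0.037,0.062,0.029,0.012,0.233,0.011
2018,-0.073,-0.012,0.004,-0.048,0.057,0.082,0.053,0.031,0.279,0.01
2017,-0.067,-0.008,0.008,-0.045,0.057,0.078,0.052,0.024,0.25,0.016
2016,-0.071,-0.031,0.008,-0.051,0.061,0.077,0.063,0.019,0.254,0.031
2015,-0.07,-0.002,0.013,-0.042,0.067,0.079,0.071,0.02,0.254,0.015
2014,-0.08,-0.008,0.01,-0.048,0.066,0.075,0.072,0.016,0.261,0.013
2013,-0.094,-0.022,0.012,-0.052,0.067,0.071,0.076,0.01,0.284,0.012
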