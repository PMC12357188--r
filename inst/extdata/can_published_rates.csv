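year,total_participants,tp_pct,tn_pct,fp_pct,fn_pct,prevalence_pct
2016,5583397,1.82,88.05,8.17,1.94,3.76
2017,5600275,1.87,87.98,8.13,2.01,3.88
2018,5519660,1.84,87.95,8.15,2.04,3.89
2019,5594791,1.57,88.43,8.42,1.56,3.13
2020,5489029,1.42,88.45,8.57,1.54,2.97
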