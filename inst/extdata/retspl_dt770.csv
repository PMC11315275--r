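frequency_hz,retspl_db_spl,ref_amplification_db,extrapolated
125,37.2,35,TRUE
250,19.6,30,FALSE
500,12.5,20,FALSE
750,7.4,15,FALSE
1000,7.5,15,FALSE
1500,6.1,15,FALSE
2000,7.9,15,FALSE
3000,6.3,15,FALSE
4000,-3.9,15,FALSE
6000,22.8,20,FALSE
8000,23,15,FALSE
10000,27.5,25,FALSE
12500,26.7,25,FALSE
14000,33.3,35,TRUE
16000,52.8,50,TRUE
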