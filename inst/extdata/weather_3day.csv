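# swpclim example fixture: three days of station weather, hand-written
date,tmax_c,tmin_c,rhmin_pct,rhmax_pct,radiation_mj_m2,wind_ms,rain_mm
2018-06-11,28.4,14.2,38,92,27.1,2.1,0
2018-06-12,33.0,16.8,30,88,28.5,1.7,0
2018-06-13,24.9,15.1,55,97,14.2,3.4,6.5
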