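ptt_area,f_depth_m,f_size_km2,rday_depth_m,rday_size_km2,rnight_depth_m,rnight_size_km2,c_depth_m,c_size_km2
108507,2.4,0.034,9.8,0.017,,,,
108508,2.9,0.108,9.3,0.004,9.7,0.0025,,
120325,1.3,0.023,6.7,0.005,6.6,0.0095,10.0,0.487
120326,2.9,0.033,,,1.6,0.0046,,
132092,1.6,0.014,7.6,0.060,3.5,0.0560,,
132093,2.4,0.032,5.3,0.011,4.8,0.0119,,
140712a,3.0,0.198,7.8,0.018,10.7,0.0101,9.6,0.667
140712b,,,,,11.5,0.0033,12.4,0.527
140713,1.7,0.053,9.5,0.019,,,,
151800,3.4,0.145,,,,,,
151801,6.8,0.007,,,,,,
163691a,3,0.022,,,,,,
163691b,8.4,0.003,,,,,,
163692,3,0.055,,,9.2,0.0039,10.1,0.042
163693a,2.1,0.022,,,,,,
163693b,2.7,0.080,,,,,,
172208,3,0.088,,,,,10.5,0.014
172209a,3,0.018,,,10.3,0.003,,
172209b,8.4,0.049,,,,,,
174108,3.0,0.034,,,10.7,0.006,9.9,0.005
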