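ptt,residency_months,single_site,n_sets,n_captures
108507,108,yes,8,4
108508,93,yes,16,3
120325,144,yes,26,4
120326,109,yes,11,4
132092,135,yes,31,6
132093,140,yes,10,2
140712,25,yes,5,1
140713,173,yes,32,2
151800,2,lt1yr,,
151801,4,lt1yr,,
163691,40,lt1yr,8,2
163692,23,yes,3,2
163693,141,yes,11,7
172208,11,lt1yr,,
172209,181,no,,
174108,70,no,,4
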