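state,baseline,f1,f2,f3,f4,published_change_pct
no_component,1604,672,917,1154,1248,-22.1
dyslipidemia,3902,2872,2112,1037,705,-81.9
hyperglycemia,143,96,279,303,456,218.8
hypertension,106,38,72,67,139,31.1
obesity,1360,927,1370,2462,2725,100.3
dyslipidemia+hyperglycemia,350,538,737,351,333,-4.8
dyslipidemia+hypertension,264,190,178,94,97,-63.2
dyslipidemia+obesity,3325,4864,3767,3002,2017,-39.3
hyperglycemia+hypertension,26,22,79,50,118,353.8
hyperglycemia+obesity,190,183,379,978,1192,527.3
hypertension+obesity,233,128,131,284,508,118.0
mets,1379,2352,2861,3100,3344,142.4
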