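treatment,added_mmol,fe3,no3,so4,dechlorination,total_consumed_mmol
control,3.60,1.65,0,0.72,0.021,2.391
molybdate_20mM,3.60,1.22,0,0.24,0.021,1.481
sulfate_5mM,3.60,1.78,0,1.26,0.020,3.060
sulfate_20mM,3.60,1.91,0,2.84,0.020,4.770
nitrate_5mM,3.60,1.65,0.375,0.75,0.021,2.796
nitrate_10mM,3.60,1.56,0.75,0.76,0.022,3.092
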