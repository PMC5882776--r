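process,treatment,unit,a,b,k,vmax,t_vmax,r2
sulfate_reduction,control,mM,5.91,9.03,0.21,0.31,10.48,0.98
sulfate_reduction,sulfate_5mM,mM,9.90,50.71,0.35,0.87,11.22,0.99
sulfate_reduction,sulfate_20mM,mM,23.85,37.91,0.24,1.43,15.15,0.97
sulfate_reduction,nitrate_5mM,mM,6.11,10.37,0.23,0.35,10.17,0.98
sulfate_reduction,nitrate_10mM,mM,6.44,17.52,0.21,0.34,13.63,0.99
fe3_reduction,control,mM,119.74,179.09,0.76,22.75,6.83,0.99
fe3_reduction,molybdate_20mM,mM,86.85,37.79,0.65,14.11,5.59,0.99
fe3_reduction,sulfate_5mM,mM,120.76,10.09,0.29,8.76,7.97,0.99
fe3_reduction,sulfate_20mM,mM,133.17,12.14,0.32,10.65,7.80,0.99
fe3_reduction,nitrate_5mM,mM,109.36,11.78,0.40,10.94,6.17,0.98
fe3_reduction,nitrate_10mM,mM,101.27,19.21,0.49,12.41,6.03,0.99
pcp_degradation,control,uM,149.61,170.26,0.52,19.45,9.88,1.00
pcp_degradation,molybdate_20mM,uM,146.70,38.71,0.31,11.37,11.79,0.99
pcp_degradation,sulfate_5mM,uM,151.48,120.02,0.42,15.91,11.40,1.00
pcp_degradation,sulfate_20mM,uM,151.42,225.02,0.45,17.03,12.04,1.00
pcp_degradation,nitrate_5mM,uM,149.36,364.05,0.54,20.16,10.92,1.00
pcp_degradation,nitrate_10mM,uM,148.63,262.50,0.50,18.58,11.14,1.00
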