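scenario,flow_L_min,variable,pmax,pmax_se,alpha,alpha_se,ek,ek_se,n
ambient,0.5,do,32.44,3.58,0.16,0.02,210.97,29.78,5
ambient,1.4,do,20.54,1.96,0.10,0.01,203.98,18.09,5
future,0.5,do,42.59,4.00,0.23,0.01,182.67,9.66,5
future,1.4,do,22.56,2.58,0.15,0.01,152.52,7.55,5
ambient,0.5,dic,19.15,1.45,0.16,0.01,121.89,16.76,5
ambient,1.4,dic,7.32,0.01,0.08,0.01,89.03,7.45,5
future,0.5,dic,25.79,3.69,0.17,0.03,174.37,40.15,5
future,1.4,dic,22.89,9.28,0.14,0.05,134.82,68.42,5
ambient,0.5,ph,0.05,0.00,0.000476,0,104.93,13.21,5
ambient,1.4,ph,0.02,0.00,0.000324,0,61.77,0.00,5
future,0.5,ph,0.13,0.02,0.000554,0,234.83,54.30,5
future,1.4,ph,0.11,0.08,0.000658,0,167.29,43.85,5
ambient,0.5,omega,0.17,0.00,0.001341,0,126.82,16.66,5
ambient,1.4,omega,0.06,0.00,0.000619,0,96.89,7.49,5
future,0.5,omega,0.11,0.02,0.000750,0,146.67,56.24,5
future,1.4,omega,0.08,0.03,0.000740,0,108.18,37.77,5
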