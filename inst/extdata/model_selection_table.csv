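model,intercept,date,deg72,ice_north,lat24,duration,df,logLik,aic,delta_aic
1,-2.38,0.48,,,1.74,0.59,4,-52.98,114.00,0.00
2,-2.44,1.22,,-0.79,1.75,0.64,5,-52.03,114.10,0.11
3,-2.33,,,,1.76,0.46,3,-54.50,115.00,1.04
4,-2.37,0.48,0.10,,1.71,0.59,5,-52.95,115.90,1.94
5,-2.42,1.21,0.10,-0.78,1.72,0.64,6,-52.00,116.00,2.05
6,-2.34,,,0.24,1.75,0.51,4,-54.06,116.10,2.17
7,-2.31,,0.13,,1.72,0.47,4,-54.44,116.90,2.94
8,-2.27,,,,1.85,,2,-57.00,118.00,4.04
9,-2.32,,0.11,0.24,1.72,0.51,5,-54.03,118.00,4.10
10,-2.28,0.26,,,1.85,,3,-56.48,119.00,5.00
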