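species,model,scenario,year,expansion_mkm2,contraction_mkm2,no_change_mkm2,overlap_pct
sacchariflorus,BCM,A2,2050,1.54,5.74,34.81,86
sacchariflorus,BCM,A2,2080,2.28,13.99,26.56,65
sacchariflorus,BCM,B1,2050,1.10,3.88,36.67,90
sacchariflorus,BCM,B1,2080,1.35,7.16,33.38,82
sacchariflorus,CGCM,A2,2050,3.08,11.94,16.51,58
sacchariflorus,CGCM,A2,2080,5.08,18.20,10.25,36
sacchariflorus,CGCM,B1,2050,2.33,9.56,18.89,66
sacchariflorus,CGCM,B1,2080,2.73,11.41,17.04,60
sinensis,BCM,A2,2050,2.08,5.85,48.85,89
sinensis,BCM,A2,2080,2.78,11.79,42.91,78
sinensis,BCM,B1,2050,1.95,3.85,50.84,93
sinensis,BCM,B1,2080,1.60,6.72,47.98,88
sinensis,CGCM,A2,2050,3.68,9.36,33.10,78
sinensis,CGCM,A2,2080,6.01,15.17,27.29,64
sinensis,CGCM,B1,2050,2.84,7.47,35.00,82
sinensis,CGCM,B1,2080,3.51,8.60,33.86,80
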