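comparison,species,within,year,agreement
model,sacchariflorus,A2,2050,0.58
model,sacchariflorus,A2,2080,0.44
model,sacchariflorus,B1,2050,0.64
model,sacchariflorus,B1,2080,0.63
model,sinensis,A2,2050,1.17
model,sinensis,A2,2080,0.96
model,sinensis,B1,2050,1.21
model,sinensis,B1,2080,1.22
scenario,sacchariflorus,BCM,2050,13.68
scenario,sacchariflorus,BCM,2080,3.23
scenario,sacchariflorus,CGCM,2050,5.28
scenario,sacchariflorus,CGCM,2080,1.33
scenario,sinensis,BCM,2050,16.35
scenario,sinensis,BCM,2080,6.25
scenario,sinensis,CGCM,2050,11.74
scenario,sinensis,CGCM,2080,3.25
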