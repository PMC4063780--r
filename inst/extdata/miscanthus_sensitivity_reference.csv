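species,parameter,value,ei0,ei1_10,ei10_20,ei20_30,ei30_100,bold
sacchariflorus,DV0,4,-0.61,0.98,1.17,-1.08,2.50,00000
sacchariflorus,DV0,6,0.69,-1.39,-1.28,2.13,-3.01,00000
sacchariflorus,DV1,14,-0.14,-2.13,0.19,-1.66,3.68,00000
sacchariflorus,DV1,16,0.12,2.15,0.11,2.67,-4.32,00000
sacchariflorus,DV2,27,0.06,5.31,9.94,-0.27,-11.68,01101
sacchariflorus,DV2,29,-0.07,-5.62,-7.63,-2.98,12.25,01101
sacchariflorus,DV3,31,0.54,10.64,-0.84,-7.20,-9.72,01011
sacchariflorus,DV3,33,-0.15,-5.80,-4.26,3.08,7.80,01101
sacchariflorus,SM0,0.225,-0.77,1.62,1.62,-0.10,2.03,00000
sacchariflorus,SM0,0.275,0.71,-1.43,-1.67,0.57,-2.10,00000
sacchariflorus,SM1,0.72,-0.28,-3.06,-0.42,-2.27,6.18,00000
sacchariflorus,SM1,0.88,0.24,4.14,-1.59,2.13,-5.68,00000
sacchariflorus,SM2,1.08,0.03,4.32,7.60,7.37,-12.94,00001
sacchariflorus,SM2,1.32,-0.01,-3.89,-6.71,-4.50,10.39,00001
sacchariflorus,SM3,1.62,0.17,7.86,7.60,1.22,-14.21,00001
sacchariflorus,SM3,1.98,-0.05,-5.12,-5.40,1.93,7.81,00000
sacchariflorus,TTCS,-6,0.76,-1.86,-2.26,-0.91,-0.83,00000
sacchariflorus,TTCS,-4,-0.78,2.32,2.42,0.37,0.67,00000
sacchariflorus,THCS,-0.00022,0.66,-2.56,-1.45,-0.44,-0.31,00000
sacchariflorus,THCS,-0.00018,-0.83,3.34,2.03,0.44,0.19,00000
sacchariflorus,DTCS,11,-0.36,0.95,1.20,0.10,0.40,00000
sacchariflorus,DTCS,13,0.38,-1.15,-0.53,-0.41,-0.57,00000
sacchariflorus,DHCS,-0.000055,0.26,-0.69,-0.39,-0.17,-0.55,00000
sacchariflorus,DHCS,-0.000045,-0.27,0.71,0.95,0.07,0.31,00000
sacchariflorus,TTHS,31,8.79,-13.96,-22.28,-21.78,-13.97,11111
sacchariflorus,TTHS,33,-8.15,26.66,16.04,8.12,8.21,11111
sacchariflorus,THHS,0.054,-0.21,0.46,0.72,0.30,0.21,00000
sacchariflorus,THHS,0.066,0.18,-0.46,-0.47,-0.41,-0.14,00000
sacchariflorus,SMDS,0.09,-0.12,-0.15,-1.64,0.98,1.39,00000
sacchariflorus,SMDS,0.11,-0.36,-1.91,-6.35,-0.91,8.48,00000
sacchariflorus,HDS,-0.022,-0.36,-1.91,-6.38,-0.88,8.48,00000
sacchariflorus,HDS,-0.018,-17.00,88.48,6.10,7.51,5.97,11000
sacchariflorus,SMWS,1.62,1.03,-2.96,-10.05,-2.71,4.37,00100
sacchariflorus,SMWS,1.98,-0.63,-2.77,-5.35,0.57,9.55,00000
sacchariflorus,HWS,0.018,-0.39,-2.08,-6.04,-0.78,8.57,00000
sacchariflorus,HWS,0.022,-0.32,-1.94,-6.52,-1.05,8.45,00000
sacchariflorus,TTHW,30,3.67,-5.43,-6.91,-9.77,-7.37,11111
sacchariflorus,TTHW,32,-1.15,2.87,3.93,0.95,1.12,00100
sacchariflorus,MTHW,0.9,0.14,-0.05,-0.58,-0.07,-0.40,00000
sacchariflorus,MTHW,1.1,-0.19,0.52,0.11,0.51,0.28,00000
sacchariflorus,PHW,0.009,-0.09,0.21,0.28,0.10,0.14,00000
sacchariflorus,PHW,0.011,0.05,-0.02,-0.22,0.00,-0.15,00000
sacchariflorus,PDD,540,-0.60,-0.53,-6.35,-0.95,8.52,00000
sacchariflorus,PDD,660,-0.13,-3.11,-6.74,-0.95,8.52,00000
sinensis,DV0,4,-0.71,0.36,1.81,-0.76,1.09,00000
sinensis,DV0,6,0.85,-1.16,-1.75,1.88,-1.30,00000
sinensis,DV1,14,-0.19,-2.45,0.79,-0.88,1.55,00000
sinensis,DV1,16,0.19,2.12,-0.79,2.61,-1.83,00000
sinensis,DV2,29,0.11,1.77,8.97,16.08,-7.08,00111
sinensis,DV2,31,-0.13,-1.01,-3.92,-13.90,5.10,00111
sinensis,DV3,34,0.26,0.46,5.41,5.22,-3.28,00111
sinensis,DV3,36,-0.12,-0.46,-1.62,-5.13,2.11,00010
sinensis,SM0,0.225,-1.46,2.97,3.59,-1.03,1.11,00000
sinensis,SM0,0.275,1.41,-2.80,-3.76,1.52,-1.17,00000
sinensis,SM1,0.72,-0.54,-3.30,1.42,-4.28,3.36,00000
sinensis,SM1,0.88,0.38,4.48,-3.69,5.13,-3.26,00000
sinensis,SM2,0.9,0.00,1.13,2.74,10.08,-3.65,00010
sinensis,SM2,1.1,-0.01,-0.91,-3.23,-8.07,3.18,00000
sinensis,SM3,2.25,0.00,1.01,4.39,13.26,-4.76,00010
sinensis,SM3,2.75,-0.01,-0.50,-2.77,-7.37,2.71,00000
sinensis,TTCS,-4,-1.10,2.60,2.67,0.88,0.26,00000
sinensis,TTCS,-6,1.00,-1.66,-4.25,-0.36,-0.25,00000
sinensis,THCS,-0.00022,0.81,-1.96,-2.80,-0.24,-0.08,00000
sinensis,THCS,-0.00018,-1.07,3.18,2.61,0.24,0.11,00000
sinensis,DTCS,13,-0.42,0.61,1.48,-0.21,0.31,00000
sinensis,DTCS,15,0.44,-0.63,-1.78,0.03,-0.23,00000
sinensis,DHCS,-0.000055,0.33,-0.23,-1.62,-0.12,-0.17,00000
sinensis,DHCS,-0.000045,-0.42,0.68,1.32,-0.12,0.28,00000
sinensis,TTHS,35,2.29,-3.12,-2.01,-7.37,-1.03,01010
sinensis,TTHS,37,-1.82,3.30,3.99,5.01,0.11,01110
sinensis,THHS,0.045,-0.05,0.10,0.16,0.09,0.00,00000
sinensis,THHS,0.055,0.08,-0.10,-0.43,-0.06,0.00,00000
sinensis,SMDS,0.09,-0.42,0.28,-2.84,0.55,1.25,00000
sinensis,SMDS,0.11,0.43,-0.02,1.39,0.21,-1.25,00000
sinensis,HDS,-0.022,0.15,0.45,0.53,0.09,-0.66,00000
sinensis,HDS,-0.018,-0.25,0.05,-1.65,0.76,0.68,00000
sinensis,SMWS,2.7,0.01,0.23,-0.20,0.00,-0.08,00000
sinensis,SMWS,3.3,-0.01,0.02,-0.03,0.03,0.02,00000
sinensis,HWS,0.045,0.00,0.00,-0.03,0.00,0.01,00000
sinensis,HWS,0.055,0.00,0.00,0.00,0.00,0.00,00000
sinensis,PDD,540,-0.27,1.21,0.03,0.00,0.00,00000
sinensis,PDD,660,0.27,-1.14,-0.16,0.00,0.00,00000
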