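mediator,nde,nde_lo,nde_hi,nie,nie_lo,nie_hi,te,te_lo,te_hi,proportion_printed
BMI >= 23 kg/m2,1.74,0.93,3.26,1.04,0.95,1.15,1.81,0.96,3.42,6.6
BMI >= 25 kg/m2,1.58,0.83,2.98,1.15,1.02,1.31,1.82,0.95,3.47,23.3
BMI >= 30 kg/m2,1.50,0.77,2.93,1.29,1.04,1.61,1.94,0.98,3.84,38.4
Gained >= 5 kg,1.95,1.05,3.61,1.02,0.97,1.08,1.99,1.07,3.69,2.9
Gained >= 10 kg,1.91,1.03,3.56,1.03,0.96,1.11,1.98,1.06,3.67,4.3
Waist >= 80 cm,1.62,0.82,3.21,1.07,0.98,1.18,1.74,0.88,3.46,12.2
Waist >= 85 cm,1.43,0.84,4.06,1.19,1.03,1.38,1.71,0.85,3.44,32.4
WHtR >= 0.5,1.43,0.70,2.93,1.09,0.97,1.21,1.56,0.76,3.20,19.4
WHtR >= 0.6,1.34,0.63,2.88,1.16,0.96,1.42,1.57,0.76,3.27,32.9
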