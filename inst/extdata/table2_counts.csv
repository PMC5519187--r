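sex,ssb_level,cases,at_risk
men,rarely,236,8860
men,1-6 per week,168,7516
men,>=1 per day,33,1083
women,rarely,142,13291
women,1-6 per week,88,7133
women,>=1 per day,28,1292
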