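age_months,label,adjuvant,al_mg
2,DTaP-IPV-Hib-HepB,AH,0.5
2,DTaP-IPV-Hib-HepB,AP,0.32
2,PCV13/15,AP,0.125
2,MenB,AH,0.5
4,DTaP-IPV-Hib-HepB,AH,0.5
4,DTaP-IPV-Hib-HepB,AP,0.32
4,PCV13/15,AP,0.125
4,MenB,AH,0.5
11,DTaP-IPV-Hib-HepB,AH,0.5
11,DTaP-IPV-Hib-HepB,AP,0.32
11,PCV13/15,AP,0.125
12,MenB,AH,0.5
12,MenC,AH,0.5
60,TdaP,AH,0.3
60,TdaP,AP,0.2
108,HPV (1st),AAHS,0.5
108,TdaP-IPV,AH,0.3
108,TdaP-IPV,AP,0.2
120,HPV (2nd),AAHS,0.5
228,TdaP,AH,0.3
228,TdaP,AP,0.2
348,Td,AH,0.5
468,Td,AH,0.5
588,Td,AH,0.5
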