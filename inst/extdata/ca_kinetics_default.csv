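age_years,v_acc_mg_d,v_res_mg_d,m_ca_g
0,160,70,28
0.25,170,80,35
0.5,180,100,45
1,200,120,60
2,220,150,90
5,250,200,180
10,350,250,400
13,500,320,600
16,450,380,800
20,410,395,950
30,400,400,1000
40,400,400,1000
50,400,400,1000
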