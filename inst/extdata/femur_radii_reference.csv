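subject,age,sex,whole_outer,whole_inner,proximal_outer,proximal_inner,middle_outer,middle_inner,distal_outer,distal_inner
S01,24,F,1631,1883,340,811,1883,1404,653,671
S02,27,F,1338,1600,379,1043,1546,1577,983,712
S03,38,F,1105,982,311,632,1089,967,673,452
S04,20,F,1730,1604,432,574,1671,1520,1041,693
S05,31,F,1299,1183,770,1005,1193,1217,604,629
S06,37,M,1696,1614,392,632,1486,1812,907,871
S07,40,M,1087,899,436,696,1179,1172,746,1032
S08,43,M,1094,1117,379,795,1418,1166,1098,905
S09,57,M,1112,1038,534,758,1068,1117,715,693
S10,27,M,1330,1019,550,510,1413,1676,558,405
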