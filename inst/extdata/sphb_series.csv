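label,n,m,s,n_c,m_c,s_c
Berkow 2011,29,-0.30,1.05,,,
Causey 2011,25,-0.30,1.05,,,
Lamhaut 2011,44,0.00,1.40,,,
Miller 2011,20,0.30,1.79,,,
Applegate 2012,91,0.50,1.43,,,
Butwick 2012-preop,50,1.20,1.07,,,
Butwick 2012-postop,50,0.10,1.28,,,
Butwick 2012-24 h,50,1.40,0.99,,,
Colquhoun 2012,20,-1.30,1.94,,,
Park 2012,40,0.90,1.33,,,
Vos 2012,30,-0.20,1.02,,,
Dewhirst 2013,45,-0.10,1.48,,,
Giraud 2013,53,1.00,1.20,,,
Isosu 2013,92,0.20,1.50,71,-0.70,1.10
Skelton 2013-preop,137,0.60,1.48,,,
Skelton 2013-postop,137,1.60,1.56,,,
Toyoda 2014-tHbLow,21,1.20,1.10,,,
Toyoda 2014-tHbMed,155,-0.20,1.30,,,
Toyoda 2014-tHbHigh,49,-1.00,1.10,,,
Miyashita 2014-R1-25,71,0.60,0.96,71,0.15,0.57
Miyashita 2014-R1-25a,73,0.68,1.02,73,0.16,0.77
Kim 2014-pre,52,0.12,1.09,,,
Kim 2014-Lefort,52,0.07,0.94,,,
Kim 2014-BSSO,52,-0.09,0.98,,,
Kim2014 post,52,-0.90,0.85,,,
Patino 2014,140,0.40,1.28,140,0.10,1.20
Yamaura 2014-0-1,115,0.33,1.41,,,
Yamaura 2014-1-2,30,-0.31,1.24,,,
Yamaura 2014-2-3,18,-0.59,1.11,,,
Yamaura 2014-3-,12,-0.53,0.87,,,
Saito 2015-Dilution,24,1.43,1.24,,,
Saito 2015-Transfusion,24,1.10,1.23,,,
Awada 2015-Precision,83,0.00,0.79,,,
Frasca 2015,41,-0.40,1.40,41,-0.30,1.10
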