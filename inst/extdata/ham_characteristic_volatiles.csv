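no,compound,threshold_ug_per_kg,chemical_class,descriptor,relative_content_percent,roav_reported
1,Pentanal,12.00,aldehyde,"pungent, grassy",1.2274,2.3998
2,Hexanal,4.00,aldehyde,"grassy at low levels, fishy at high levels",4.6181,27.0866
3,Heptanal,3.00,aldehyde,"fatty, green",0.9151,7.1566
4,Octanal,1.40,aldehyde,"sweet orange, honey; grassy at low levels",0.6394,10.7155
5,Nonanal,1.00,aldehyde,"plastic, fishy",0.1004,2.3544
6,Benzaldehyde,3.00,aldehyde,"almond, bitter almond, peach kernel",1.6205,12.6729
7,Isopropyl Alcohol,40000.00,alcohol,"mild, alcoholic",0.0010,5.7935e-7
8,Ethanol,8.00,alcohol,"alcoholic, slightly sweet",1.1285,3.3096
9,2-Butanol,43000.00,alcohol,winey,0.0324,1.7704e-5
10,1-Octen-3-ol,1.00,alcohol,mushroom,4.2624,100.0000
11,1-Heptanol,3.00,alcohol,"green, fatty",0.5823,4.5535
12,"4-Heptanol, 2,6-dimethyl-",1300.00,alcohol,herbaceous,0.0020,3.6283e-5
13,Benzyl alcohol,1.20,alcohol,"floral, sweet",0.0678,1.3258
14,"5-Hepten-2-ol,6-methyl-",2000.00,alcohol,"citrus, green",0.0006,7.1909e-6
15,1-Octen-3-one,0.05,ketone,"mushroom, metallic",0.0627,29.4274
16,"Butanoic acid, ethyl ester",0.10,ester,"fruity, pineapple",0.0104,2.4337
17,"Butanoic acid, 2-methyl-, ethyl ester",0.01,ester,"fruity, apple",0.0024,5.7434
18,"Butanoic acid, 3-methyl-, ethyl ester",0.01,ester,"fruity, sweet",0.0033,7.7816
19,"Hexanoic acid, ethyl ester",0.30,ester,"pineapple-like, fruity",0.0375,2.9309
20,"Acetic acid, 2-phenylethyl ester",3000.00,ester,"rose, honey",0.0031,2.4501e-5
21,"Hexadecanoic acid, ethyl ester",2000.00,ester,"waxy, faint fruity",0.0064,7.5155e-5
22,"Octanoic acid, methyl ester",200.00,ester,"fruity, winey",0.0004,4.5969e-5
23,Tetradecanoic acid,10000.00,acid,"faint, waxy",0.0008,1.9034e-6
24,n-Hexadecanoic acid,10000.00,acid,"faint, oily",0.0163,3.8225e-5
25,Pyrazine,175000.00,other,"nutty, roasted",0.0449,6.0243e-6
26,Pyrrole,20000.00,other,"nutty, sweet",0.0133,1.5546e-5
27,"Ethanone, 1-(1H-pyrrol-2-yl)-",170000.00,other,"musty, nutty",0.0046,6.3212e-7
28,Caffeine,29000.00,other,nearly odorless,0.0003,2.4773e-7
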