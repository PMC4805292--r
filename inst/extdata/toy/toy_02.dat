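# pmfkd timeseries (time_ps z_A)
# save_interval_ps: 0.5
# n_rows: 80
0.5 2.0212349296645935
1 1.488457436574635
1.5 0.84188893187619662
2 1.2045450322599929
2.5 1.2740661912232354
3 1.2033874799903399
3.5 0.95038286108644854
4 1.4175153611239439
4.5 2.4032934932562697
5 3.2572048575153816
5.5 1.3066836771574519
6 2.050241886864772
6.5 1.3121063799345447
7 1.2459730147763601
7.5 1.3240890539336514
8 1.5192680164187891
8.5 2.5789252571450669
9 3.0956399459780761
9.5 2.1160828635545177
10 1.1415832444132787
10.5 1.8520745200438617
11 1.4371427823218395
11.5 0.69398705683197814
12 0.50244710995724395
12.5 1.4821246833468047
13 1.4241068142336342
13.5 2.0009449410578086
14 1.9485401827042246
14.5 2.0101798294259439
15 1.746465809973335
15.5 2.5345820509423662
16 2.5076712489863699
16.5 2.0779898639843499
17 0.65560616272033767
17.5 1.2715596732940206
18 0.84872124282000794
18.5 1.6459531942137289
19 1.4045790464542391
19.5 2.0714687271050032
20 0.70328121185603987
20.5 0.38326021355369277
21 1.0698527408443996
21.5 1.159700031296458
22 2.3183576285099048
22.5 2.3306778779869783
23 1.7036973425086133
23.5 1.2010946561279998
24 1.8691267747296609
24.5 1.455279468584795
25 1.459489876878157
25.5 0.23120839731530449
26 0.55731091051560011
26.5 1.2122506793877976
27 2.0707025835803665
27.5 1.070515788781079
28 1.3215110555400891
28.5 1.9695332393411062
29 1.5426511612964193
29.5 1.5484571799024534
30 1.797223954244674
30.5 2.9107031286661931
31 1.4776191100133578
31.5 1.5594719392470089
32 1.0682116627479976
32.5 1.5133639321032042
33 1.0026837033317071
33.5 0.89433896626617271
34 0.91224736215172353
34.5 0.78919891432411915
35 -0.0056755622529717636
35.5 0.61483449961565972
36 1.0064501942004187
36.5 1.1377709443479889
37 1.1428969141357226
37.5 1.3325201017364694
38 1.6925055158117581
38.5 1.5223421373390897
39 1.3523468924044051
39.5 1.9020143094027691
40 1.9729621093016714
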