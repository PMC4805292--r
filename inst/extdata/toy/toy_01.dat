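# pmfkd timeseries (time_ps z_A)
# save_interval_ps: 0.5
# n_rows: 80
0.5 -0.44189972035321756
1 0.7199118311279229
1.5 0.41535128827314727
2 0.50092342939805679
2.5 0.08840338671041767
3 0.64603292690903502
3.5 0.3573526477499756
4 -0.78883803139182695
4.5 -0.074740354533504222
5 -0.10595262876559064
5.5 -0.61009311395524524
6 -0.86266679627983023
6.5 -0.76863033630308508
7 -0.76855121546346949
7.5 0.14272992963439041
8 0.88253867024352162
8.5 0.53818809933069223
9 0.59304088371246189
9.5 -0.53448177163552146
10 -0.98855913098715475
10.5 -0.14048062226687758
11 -0.97215256542624096
11.5 -0.83332610197547541
12 -0.20758741088647151
12.5 -0.10702648247470782
13 -0.91590658690196958
13.5 -0.79912054531143761
14 -0.30160348705427753
14.5 0.67233058922099942
15 -0.78387128054823196
15.5 0.20458013666993796
16 -0.54233723852458471
16.5 0.57976411163208663
17 -0.3284546657223929
17.5 -0.021392132697855892
18 -0.28860523362630019
18.5 -0.06704761793777371
19 -0.062618171016246615
19.5 0.12940998126322634
20 0.83613380231653522
20.5 0.65518683189940796
21 -0.08038728198675138
21.5 0.21419241405858847
22 0.26605310817475325
22.5 1.023989799882862
23 -0.36721665112146434
23.5 -0.89132803416560935
24 0.14108059560379932
24.5 -0.95525532794482404
25 -0.68735996938166677
25.5 0.67364979247228673
26 0.74138774399252072
26.5 0.34712989827144852
27 1.782057084437912
27.5 1.4559900395168572
28 0.84495597411656165
28.5 0.23111162291660414
29 0.32408778774123093
29.5 0.46920452946870111
30 0.061982407165156017
30.5 0.25495546909932054
31 0.23680090880331228
31.5 0.44532339800819165
32 1.315976434660018
32.5 0.85981907299899829
33 -0.2030225458505589
33.5 -0.01268331947648485
34 -0.1736216816913268
34.5 0.60703193765176677
35 0.40828818855119997
35.5 0.29536062306943633
36 0.3794745488034641
36.5 0.046619586656179504
37 -1.035262718343263
37.5 -0.1971167265420643
38 0.12070956273238533
38.5 -0.51425929990411545
39 -0.10063194686539889
39.5 1.0273017665331414
40 -0.54072480057139205
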