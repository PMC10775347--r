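 39.8271232
 42.8271232
 45.8271232
 48.8271232
 51.8271232
 54.8271232
 57.8271232
 60.8271232
 63.8271232
 66.8271232
 69.8271232
72.20175233
69.20175233
66.20175233
63.20175233
60.20175233
57.20175233
54.20175233
51.20175233
48.20175233
45.20175233
42.20175233
39.20175233
36.20175233
33.20175233
30.26795703
31.79815961
33.32836219
34.85856478
36.38876736
37.91896994
  39.043693
40.16841605
41.29313911
42.41786216
43.54258522
44.66730827
45.79203133
46.91675438
48.04147744
49.16620049
 52.0003334
 54.8344663
 57.6685992
 60.5027321
  63.336865
 66.1709979
 69.0051308
 71.8392637
 74.6733966
77.50752951
74.50752951
71.50752951
68.50752951
65.50752951
62.50752951
59.50752951
56.50752951
53.50752951
50.50752951
47.50752951
44.50752951
41.50752951
38.50752951
35.50752951
32.50752951
29.50752951
27.74501049
29.73519918
31.72538788
33.71557657
34.69954152
35.68350647
36.66747143
37.65143638
38.63540134
39.61936629
40.60333124
 41.5872962
42.57126115
43.55522611
42.43120766
41.30718922
40.18317077
39.05915233
37.93513388
36.81111544
35.68709699
34.56307855
33.43906011
32.31504166
32.59120866
32.86737566
33.14354266
33.41970966
33.69587666
33.97204366
34.24821066
34.52437766
34.80054466
35.07671166
35.41383176
35.75095186
36.08807196
36.42519207
36.76231217
37.09943227
37.43655238
37.77367248
38.11079258
38.44791269
39.21386574
39.97981879
40.74577184
41.51172489
42.27767794
43.04363099
43.80958404
44.57553709
45.34149014
46.10744319
49.03806634
 51.9686895
54.89931266
57.82993582
60.76055898
63.69118214
 66.6218053
69.55242846
72.48305161
75.41367477
72.41367477
69.41367477
66.41367477
63.41367477
60.41367477
57.41367477
54.41367477
51.41367477
48.41367477
45.41367477
42.41367477
39.41367477
36.41367477
33.41367477
30.41367477
27.41367477
24.41367477
21.41367477
18.41367477
15.41367477
12.41367477
10.73849695
10.02118483
 9.30387271
8.586560591
7.869248473
7.151936355
6.434624237
5.717312118
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
5.353400553
5.706801105
6.060201658
6.413602211
6.767002763
7.120403316
7.473803868
7.827204421
8.180604974
8.534005526
8.180604974
7.827204421
7.473803868
7.120403316
6.767002763
6.413602211
6.060201658
5.706801105
5.353400553
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          8
         11
         14
         17
         20
         23
         26
         29
         32
         35
         38
         41
         44
         47
         50
         53
         56
         59
         62
         65
         68
         71
         74
         77
         80
         83
         86
         89
         90
         90
89.62438817
89.24877634
88.87316451
88.49755268
88.12194084
87.74632901
87.37071718
86.99510535
86.61949352
86.24388169
84.75176605
83.25965042
81.76753478
80.27541914
78.78330351
77.29118787
75.79907223
 74.3069566
72.81484096
71.32272532
71.65733573
71.99194613
72.32655654
72.66116694
72.99577735
73.33038776
73.66499816
73.99960857
74.33421897
74.66882938
 73.9210879
73.17334642
72.42560494
71.67786346
70.93012199
70.18238051
69.43463903
68.68689755
67.93915607
67.19141459
65.54521664
63.89901868
62.25282073
60.60662277
58.96042482
57.31422686
 55.6680289
54.02183095
52.37563299
50.72943504
48.42437787
 46.1193207
43.81426353
41.50920637
 39.2041492
36.89909203
34.59403486
32.28897769
29.98392053
27.67886336
25.41097702
23.14309069
20.87520435
18.60731801
16.33943168
14.07154534
11.80365901
9.535772671
7.267886336
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
7.521145456
10.04229091
12.56343637
15.08458182
17.60572728
20.12687274
22.64801819
25.16916365
27.69030911
30.21145456
29.07000313
27.92855169
26.78710026
25.64564882
24.50419739
23.36274595
22.22129452
21.07984309
19.93839165
18.79694022
21.79694022
24.79694022
27.79694022
30.79694022
33.79694022
36.79694022
39.79694022
42.79694022
45.79694022
48.79694022
51.79694022
54.79694022
57.79694022
60.79694022
63.79694022
66.79694022
69.79694022
72.79694022
75.79694022
78.79694022
75.79694022
72.79694022
69.79694022
66.79694022
63.79694022
60.79694022
57.79694022
54.79694022
51.79694022
48.79694022
45.79694022
42.79694022
39.79694022
36.79694022
33.79694022
30.79694022
27.79694022
24.79694022
21.79694022
19.22984332
19.08044234
18.93104137
18.78164039
18.63223942
18.48283845
18.33343747
 18.1840365
18.03463552
17.88523455
17.73583358
16.48975598
15.24367838
13.99760078
12.75152318
11.50544558
10.25936798
9.013290385
7.767212787
6.521135188
 5.27505759
5.247551831
5.220046072
5.192540313
5.165034554
5.137528795
5.110023036
5.082517277
5.055011518
5.027505759
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
5.622719435
 6.24543887
6.868158305
 7.49087774
8.113597175
8.736316609
9.359036044
9.981755479
10.60447491
11.22719435
14.22719435
17.22719435
20.22719435
23.22719435
26.22719435
29.22719435
32.22719435
35.22719435
38.22719435
41.22719435
44.22719435
47.22719435
50.22719435
53.22719435
56.22719435
59.22719435
62.22719435
65.22719435
68.22719435
71.22719435
74.22719435
77.22719435
80.22719435
83.22719435
86.05356077
86.84284861
87.63213646
88.42142431
89.21071215
         90
88.52982799
87.05965598
85.58948397
84.11931196
82.64913995
81.17896793
79.70879592
78.23862391
 76.7684519
75.29827989
74.18456219
73.07084448
71.95712678
70.84340908
69.72969137
68.61597367
67.50225596
66.38853826
65.27482056
64.16110285
63.91419234
63.66728182
63.42037131
 63.1734608
62.92655028
62.67963977
62.43272925
62.18581874
61.93890822
61.69199771
62.35203581
63.01207392
63.67211202
64.33215013
64.99218823
65.65222633
66.31226444
66.97230254
67.63234065
68.29237875
68.53445025
68.77652176
69.01859326
69.26066477
69.50273627
69.74480778
69.98687928
70.22895079
70.47102229
 70.7130938
70.55294853
70.39280326
70.23265799
70.07251272
69.91236745
69.75222218
69.59207691
69.43193164
69.27178637
 69.1116411
70.06079921
71.00995732
71.95911543
72.90827354
73.85743166
74.80658977
75.75574788
76.70490599
 77.6540641
78.60322222
79.08647194
79.56972166
80.05297138
80.53622111
81.01947083
81.50272055
81.98597028
   82.46922
82.95246972
83.43571944
 84.0921475
84.74857556
85.40500361
86.06143167
86.71785972
87.37428778
88.03071583
88.68714389
89.34357194
         90
         87
         84
         81
         78
         75
         72
         69
         66
         63
         60
         57
         54
         51
         48
         45
         42
         39
         36
         33
         30
         27
         24
         21
         18
         15
         12
9.085568683
7.723712455
6.361856228
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
          5
6.717624371
8.435248743
10.15287311
11.87049749
13.58812186
15.30574623
 17.0233706
18.74099497
20.45861934
22.17624371
23.25710511
24.33796651
25.41882791
 26.4996893
 27.5805507
 28.6614121
 29.7422735
30.82313489
31.90399629
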