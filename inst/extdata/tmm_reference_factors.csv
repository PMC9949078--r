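seed,sample,factor
1,S1,0.999775155109
1,S2,0.87743947406
1,S3,1.04420686495
1,S4,1.08457709674
1,S5,1.11472251506
1,S6,0.90295632647
2,S1,1.0051705909
2,S2,1.01710529839
2,S3,1.04782058746
2,S4,1.1679853579
2,S5,0.873927001617
2,S6,0.914523408335
3,S1,1.14506372006
3,S2,1.07487269776
3,S3,0.912301073104
3,S4,0.970421227414
3,S5,0.940261258459
3,S6,0.976037036366
4,S1,1.05466278072
4,S2,1.1700234493
4,S3,0.975245915588
4,S4,0.774980835328
4,S5,1.03589615609
4,S6,1.03507183116
5,S1,0.89649025021
5,S2,0.929005344391
5,S3,0.963790309997
5,S4,1.18655642971
5,S5,1.15606653624
5,S6,0.908201958419
6,S1,1.0682659234
6,S2,0.932594962191
6,S3,1.02627112105
6,S4,1.1070702336
6,S5,0.9052975078
6,S6,0.975885697505
7,S1,0.871179658241
7,S2,0.813701391106
7,S3,1.17407803168
7,S4,1.14799360181
7,S5,1.24281200693
7,S6,0.842142034851
8,S1,0.888750335461
8,S2,1.02392948006
8,S3,1.01492460948
8,S4,0.980055760431
8,S5,1.0816693847
8,S6,1.02134171132
9,S1,0.950813481471
9,S2,0.97169491545
9,S3,0.842841678715
9,S4,1.07939808935
9,S5,1.14128257152
9,S6,1.04244681131
10,S1,1.07797783425
10,S2,1.03052767111
10,S3,0.959241956724
10,S4,1.10766524783
10,S5,1.03052210948
10,S6,0.822122437238
11,S1,0.972297527368
11,S2,1.06852088054
11,S3,0.997482548544
11,S4,0.979556144644
11,S5,0.912122084607
11,S6,1.08001601314
12,S1,0.931309095356
12,S2,1.01953129306
12,S3,1.04762901306
12,S4,1.07029100703
12,S5,1.01274786234
12,S6,0.92745931289
13,S1,0.787304981239
13,S2,1.03626131834
13,S3,1.08500746318
13,S4,1.01256519617
13,S5,1.03511395384
13,S6,1.07781402208
14,S1,0.999873742236
14,S2,0.932859863852
14,S3,1.03203122299
14,S4,1.05349395845
14,S5,1.04400179243
14,S6,0.944522478814
15,S1,1.03968372787
15,S2,0.912505636453
15,S3,1.00347118144
15,S4,1.07446648303
15,S5,0.962749588789
15,S6,1.01543488272
16,S1,0.960010688063
16,S2,1.01386137809
16,S3,1.14137725389
16,S4,1.00887238423
16,S5,0.890793436615
16,S6,1.00161978883
17,S1,1.00470516962
17,S2,0.902146427893
17,S3,1.01419211473
17,S4,1.05840466146
17,S5,0.920410797807
17,S6,1.11668491851
18,S1,1.11296197169
18,S2,1.06647297749
18,S3,0.95296594064
18,S4,1.06709699285
18,S5,1.01500670373
18,S6,0.816243307088
19,S1,1.14235432334
19,S2,1.0536150718
19,S3,1.02283309714
19,S4,0.811995112784
19,S5,0.914983697219
19,S6,1.0933158692
20,S1,0.873200715265
20,S2,1.00398658996
20,S3,1.10968262809
20,S4,0.956971007255
20,S5,1.0856959099
20,S6,0.98935518855
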