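ratio,gene,condition,replicate,cq
1,housek,0,rep1,19.6508048173348
1,target,0,rep1,19.6080132338901
0,housek,1,rep1,22.0284709198155
0.001,housek,1,rep1,22.1393327457894
0.005,housek,1,rep1,22.7575624126985
0.01,housek,1,rep1,21.5708173784359
0.05,housek,1,rep1,22.5406975875936
0.1,housek,1,rep1,22.061269163424
0.25,housek,1,rep1,22.15442725876
0.5,housek,1,rep1,22.4563324100074
0.75,housek,1,rep1,22.0333670522394
1,housek,1,rep1,22.4345112657922
0,target,1,rep1,31.5079196517835
0.001,target,1,rep1,30.840406330145
0.005,target,1,rep1,29.3248132126225
0.01,target,1,rep1,28.195419585981
0.05,target,1,rep1,25.9158051196626
0.1,target,1,rep1,25.3901751829575
0.25,target,1,rep1,23.7968494731014
0.5,target,1,rep1,23.0326954784165
0.75,target,1,rep1,22.4071662648862
1,target,1,rep1,21.9568637684919
1,housek,0,rep2,20.0510240323638
1,target,0,rep2,19.9839622051125
0,housek,1,rep2,22.053576864568
0.001,housek,1,rep2,22.0366853892848
0.005,housek,1,rep2,22.0100284286896
0.01,housek,1,rep2,21.8389475715467
0.05,housek,1,rep2,22.2343532963255
0.1,housek,1,rep2,21.8820498154415
0.25,housek,1,rep2,22.23124405411
0.5,housek,1,rep2,22.0562719993668
0.75,housek,1,rep2,21.7980801376323
1,housek,1,rep2,21.7842322292297
0,target,1,rep2,31.6290689184744
0.001,target,1,rep2,30.8712861450077
0.005,target,1,rep2,29.0848007050458
0.01,target,1,rep2,28.7778102705995
0.05,target,1,rep2,26.5044179119444
0.1,target,1,rep2,25.3504934805453
0.25,target,1,rep2,24.0243756539987
0.5,target,1,rep2,23.083833322715
0.75,target,1,rep2,22.5537837152027
1,target,1,rep2,22.0811745673088
1,housek,0,rep3,20.2088551934682
1,target,0,rep3,19.8416361122219
0,housek,1,rep3,22.1465197149788
0.001,housek,1,rep3,21.9372894379636
0.005,housek,1,rep3,22.0871648812142
0.01,housek,1,rep3,22.0750088125031
0.05,housek,1,rep3,22.0642039232748
0.1,housek,1,rep3,22.0351589572065
0.25,housek,1,rep3,21.989192712091
0.5,housek,1,rep3,22.2399188191729
0.75,housek,1,rep3,21.541669472751
1,housek,1,rep3,22.6243294731493
0,target,1,rep3,31.3864216017886
0.001,target,1,rep3,30.4779735258003
0.005,target,1,rep3,29.611410014828
0.01,target,1,rep3,28.3852109826752
0.05,target,1,rep3,26.2801275274838
0.1,target,1,rep3,25.0096147349242
0.25,target,1,rep3,24.2292584884321
0.5,target,1,rep3,22.865379612167
0.75,target,1,rep3,22.4099262797447
1,target,1,rep3,21.9242493709382
1,housek,0,rep4,20.2645915376611
1,target,0,rep4,19.7513594701483
0,housek,1,rep4,22.2590455280566
0.001,housek,1,rep4,22.3681024320106
0.005,housek,1,rep4,22.2314549299843
0.01,housek,1,rep4,22.2418547998737
0.05,housek,1,rep4,22.2276651425021
0.1,housek,1,rep4,22.0307842993304
0.25,housek,1,rep4,22.3312353943018
0.5,housek,1,rep4,22.1291796987234
0.75,housek,1,rep4,22.462708856515
1,housek,1,rep4,22.1890360642044
0,target,1,rep4,31.5667420606062
0.001,target,1,rep4,30.4770786624772
0.005,target,1,rep4,29.6903339736154
0.01,target,1,rep4,28.3572591366779
0.05,target,1,rep4,26.2821490571487
0.1,target,1,rep4,25.4179165676068
0.25,target,1,rep4,23.9174702438894
0.5,target,1,rep4,22.9940982553938
0.75,target,1,rep4,22.5916743911379
1,target,1,rep4,21.8195570543792
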