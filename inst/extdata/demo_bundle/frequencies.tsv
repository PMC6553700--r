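variant_key	database	allele_fraction
6:138872061:A:T	popdb	0.00170938647725231
5:114577980:T:C	popdb	0.0183264783651303
17:42718117:C:A	popdb	0.0033522117355025
4:46570390:C:T	popdb	0.000195123906850046
6:73237237:A:T	popdb	0.00919396031979668
21:143316223:G:C	popdb	0.00561721121613032
9:194934776:T:C	popdb	0.0127026857133757
10:5846773:G:T	popdb	0.000336620839826823
8:101013838:T:C	popdb	0.00766680501538928
12:69489266:G:T	popdb	0.000120998040604273
8:109236727:C:A	popdb	0.00025698599293346
7:188852469:G:T	popdb	0.00497044139919242
8:123405629:C:G	popdb	0.00077703606444864
16:111717848:T:G	popdb	0.00158553231881703
21:174616994:G:C	popdb	0.000250418775524564
8:82477681:T:A	popdb	0.000301049772476206
1:66008762:G:C	popdb	0.00749738251338949
3:3385071:A:G	popdb	0.00681528163568415
18:134853660:G:T	popdb	0.000363892218324188
15:182674681:C:A	popdb	0.000182695923372726
16:4248731:C:G	popdb	0.0153226691388478
6:16464779:C:G	popdb	0.00485493268243532
19:105097084:C:G	popdb	0.000283591941291515
X:75908541:A:C	popdb	0.000121831211162704
3:64283900:T:A	popdb	0.001
15:43395411:A:T	popdb	0.00580002935541316
2:64378480:T:G	popdb	0.027172840483982
18:32076964:G:T	popdb	0.0326405828849782
3:159810271:G:A	popdb	0.0157437728523234
13:66238432:C:T	popdb	0.00921787102278591
15:78966610:T:A	popdb	0.00384814958109144
5:113480946:C:A	popdb	0.0151044679563299
14:144370382:C:T	popdb	0.000256196844273389
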