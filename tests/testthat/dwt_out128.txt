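0.59408088826581329
0.52063451510273728
0.4421445656975217
0.38208712753587493
0.36695538652523302
0.38560923731920055
0.41655292905627572
0.45552825593080365
0.49376166573842717
0.52531883052106632
0.55328178556308105
0.55608363783525894
0.51329586567049512
0.44629791804941527
0.37910991527165144
0.34100775635209346
0.36497160987355448
0.43390497364174335
0.51645989289871985
0.6053098885452427
0.68695229252492951
0.75274371159776166
0.80635060077305287
0.81602573186381933
0.75357682503173995
0.64625227195483903
0.52393532451952529
0.43600498730810067
0.43402144920434133
0.49307068232747142
0.57344830684788328
0.64218503018199136
0.66118921660742735
0.64243088474342058
0.61336305670934776
0.57944774169866098
0.54972133219394237
0.52725066711522317
0.50675035518891787
0.50177647864531316
0.5256479520005336
0.56465304957231766
0.60322591410795046
0.6245203019233081
0.60884880861500423
0.56506562717104958
0.5113686988077395
0.44777902430549055
0.3785249832127684
0.31239499475889687
0.25123218520817314
0.22110578586277801
0.24624354911097407
0.3068103580838446
0.38002309142000862
0.43168744584935331
0.42488225431157922
0.37936789789081304
0.32609013676907561
0.28389547070962978
0.27768916226710832
0.29859961011483205
0.32432142956794557
0.36763061471356845
0.43359291680619377
0.51065050703540871
0.59657836489125093
0.63728789150524601
0.58566514425052141
0.47679838116328943
0.34569820575471716
0.28306503177413306
0.37635152435046337
0.56671485012736389
0.78111121271067308
0.90895362510760336
0.83722756312197621
0.6319785102302562
0.38975075229169331
0.20778880610184025
0.19172605620575545
0.29685278881198029
0.44154791350448946
0.5796637583604427
0.65390090776659116
0.67766161845995587
0.69218195714645014
0.68330665514589839
0.6459388875837615
0.5930047401950076
0.52444419216303384
0.49899052933546617
0.57032932312361284
0.697866190643054
0.83895492505744318
0.90448192646474057
0.80565381264706526
0.60128534895531693
0.36978461077684299
0.20504631381708963
0.20707283095607373
0.32676768229940362
0.48256014435996225
0.61788688784280721
0.66568151207741721
0.64556628237201807
0.60773718849629266
0.54967718795399778
0.47796956612772645
0.40620013752600798
0.33251336690675398
0.30833492876393975
0.38134243427109188
0.51423853921530405
0.66545066649479445
0.76311483900380039
0.73304259842466934
0.61665204883453306
0.47516183328687772
0.36704822830797779
0.35703480904592338
0.41905120939767804
0.50241770919470641
0.58419362125448571
0.63541291779073772
0.65661198047867475
0.66475481424231453
0.64739053577594674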