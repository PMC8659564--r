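0.39920174831323157
0.43473656537313726
0.47832063715742607
0.52739786650990073
0.57829925495731882
0.62494925617004415
0.6630589648946994
0.68499417678398711
0.68313874846175804
0.66175530378119574
0.62892007634040847
0.58830521593773033
0.54500445635524741
0.5047332118484511
0.47099032032987592
0.4518814637780138
0.45524786333594291
0.47730102753775022
0.51118376408623345
0.55222424551028326
0.5942824427838167
0.63420002078160076
0.67094717751161548
0.69899440103148935
0.71323614367077992
0.71492074767331981
0.70635076627206006
0.69070788510685788
0.67208546406047309
0.64990093897438894
0.62249909578490303
0.59051576733824096
0.5543429481494293
0.51529834234602667
0.47567818727122108
0.43547309421346053
0.39468372385124628
0.35628247478933661
0.32308819943921468
0.29831802346262815
0.28521624338042362
0.2824240170996149
0.28698316922624251
0.29773465385356523
0.31297059078041128
0.330608480118045
0.34928974413758213
0.36596965987171259
0.37761173163935213
0.38521889914513918
0.39081734877291907
0.39554418546506581
0.40104400956517966
0.40790963573557493
0.41591467146354671
0.42664865169930288
0.44156650923346691
0.45950076762014902
0.47900539058080921
0.49830384060152333
0.51521239642656547
0.5301502242961007
0.54425480547843996
0.5568857016015627
0.56774117122159184
0.57666563028374507
0.58261185109849412
0.58712977070082761
0.59198546444821332
0.59399833634388277
0.58977839292924727
0.57692538920876246
0.55266276325194108
0.51953618263546286
0.48293762104473797
0.44310471466413492
0.40070027822215015
0.36243226582427679
0.33420511294964705
0.32310405863853758
0.33647960947918182
0.36995089079351073
0.41452004615347748
0.4677408417604943
0.52592340031861839
0.5806938853586584
0.62562599206780123
0.65055606769357976
0.64524779909528374
0.61499377120415832
0.57031511575416038
0.51554834545619344
0.45678737858998375
0.40199229991854857
0.3564535723220329
0.33071274353470748
0.33514655559445033
0.36487774576272025
0.41039397358738883
0.46660540598528588
0.52663243952267635
0.5842169419022234
0.63566990540187784
0.67236259615481775
0.6859017175465042
0.67933081437385479
0.65908684773318882
0.62884909287400248
0.59364615025640777
0.5578309653654262
0.52400283990019925
0.49781664934245928
0.48493104673258342
0.48356592482564115
0.48928006402728752
0.50077371751363431
0.51594995899270457
0.53036066346735988
0.54062374737779495
0.54189329769999228
0.52903819695326626
0.50509466481246856
0.47656552162938814
0.44444134187096462
0.41051359412135385
0.3818996953215465
0.36432849854770794
0.36574713806663656
0.39432560232612124
0.44454800419103135
0.50577270292092491
0.57446691835685615
0.64561940053693834
0.70981734701580845
0.76007255444103961
0.78477042524006269
0.77239248081596812
0.72885624231638935
0.66574866943221234
0.58863402287008992
0.50510790560706498
0.42356397947317381
0.34949043878153424
0.29412634753481393
0.26850416397843607
0.26866696295731901
0.28614726787642925
0.3164795648704069
0.3534215156831747
0.39144654271981966
0.42741830146722576
0.45371180604814815
0.46274302433412473
0.45743356277252839
0.44403704650964798
0.42521134339850342
0.40480624239921575
0.38768890207095097
0.37696373226982938
0.37874170283199088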