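"pattern","k"
"-----+--",0.315262845203874
"-----+-+--",0.0398461229475151
"-----+-+-+",-0.453027848391374
"-----+-++-",1.24765810872263
"-----+-+++",0.758292291955987
"-----++---",-0.263106986614302
"-----++--+",-0.752341903605439
"-----++-+-",0.953891754043074
"-----++-++",0.50460413714787
"-----+++--",0.681269063040714
"-----+++-+",0.252712154964459
"-----++++-",2.01504174580942
"-----+++++",1.50000002637025
"----+---",-0.1537151751687
"----+--+-",0.380912285164144
"----+--++",-0.142134954491445
"----+-+--",0.0398457318759405
"----+-+-+",-0.45303169751629
"----+-++-",1.24764396144874
"----+-+++",0.75820578485318
"----++---",-0.26310863616018
"----++--+",-0.752356066279449
"----++-+-",0.953846406232716
"----++-++",0.504390315106875
"----+++--",0.681143230656643
"----+++-+",0.252208878380548
"----++++-",2.0139689993072
"----+++++",1.49623984380916
"---+----",-0.546619395118212
"---+---+",-1.24641210374177
"---+--+-",0.380902848713295
"---+--++",-0.142208309252612
"---+-+--",0.0398090932819413
"---+-+-+",-0.453253352782542
"---+-++-",1.24704232621002
"---+-+++",0.755934791296184
"---++---",-0.263221199020768
"---++--+",-0.752957681006277
"---++-+-",0.952404007739163
"---++-++",0.499999999832712
"---+++--",0.678077344891415
"---+++-+",0.24406520905297
"---++++-",2.00000001029642
"---+++++",1.46490355781958
"--+----",-0.546627422150169
"--+---+",-1.24654847833136
"--+--+-",0.380443015697717
"--+--++",-0.144333123126914
"--+-+--",0.0385402534407795
"--+-+-+",-0.458002310188775
"--+-++-",1.23732272164364
"--+-+++",0.732282424057578
"--++---",-0.266117729713828
"--++--+",-0.762677277502596
"--++-+-",0.934563787436073
"--++-++",0.462897970519608
"--+++--",0.648075367851493
"--+++-+",0.187174279915283
"--++++-",1.91688234268348
"--+++++",1.32912059890601
"-+----",-0.547046402190729
"-+---+",-1.2501233671597
"-+--+-",0.372006835624518
"-+--++",-0.168651529227964
"-+-+--",0.0215410367895363
"-+-+-+",-0.499999997054441
"-+-++-",1.16865151865143
"-+-+++",0.610787885226373
"-++---",-0.295915453363888
"-++--+",-0.831348449456191
"-++-+-",0.831348464627775
"-++-++",0.295915453363888
"-+++--",0.499999999988255
"-+++-+",-0.0431483636314359
"-++++-",1.60342254183687
"-+++++",0.893063732726567
"+-----",-0.893063718490581
"+----+",-1.60342251942072
"+---+-",0.0431483367202083
"+---++",-0.499999999988269
"+--+--",-0.295915453363888
"+--+-+",-0.831348449456191
"+--++-",0.831348464627775
"+--+++",0.295915453363888
"+-+---",-0.610787866773546
"+-+--+",-1.16865154526943
"+-+-+-",0.499999997054441
"+-+-++",-0.02154103678947
"+-++--",0.16865152922805
"+-++-+",-0.372006835623023
"+-+++-",1.25012337610909
"+-++++",0.547046402190635
"++-----",-1.32912057900133
"++----+",-1.91688235232624
"++---+-",-0.187174279915311
"++---++",-0.648075367848905
"++--+--",-0.462897970516529
"++--+-+",-0.93456378744387
"++--++-",0.762677277500694
"++--+++",0.266117729712237
"++-+---",-0.732282424062806
"++-+--+",-1.23732270341179
"++-+-+-",0.458002310191175
"++-+-++",-0.0385402534402955
"++-++--",0.144333123126893
"++-++-+",-0.380443015697719
"++-+++-",1.24654848732676
"++-++++",0.546627402693159
"+++-----",-1.46490356246894
"+++----+",-1.99999999393911
"+++---+-",-0.244065209055547
"+++---++",-0.6780773448914
"+++--+--",-0.499999999832724
"+++--+-+",-0.952404021112653
"+++--++-",0.752957700790097
"+++--+++",0.26322119901963
"+++-+---",-0.755934791296189
"+++-+--+",-1.24704231723813
"+++-+-+-",0.453253331983224
"+++-+-++",-0.0398090944686853
"+++-++--",0.142208309252617
"+++-++-+",-0.380902826835516
"+++-+++",0.153716631857321
"++++-----",-1.49623985958483
"++++----+",-2.0139689993112
"++++---+-",-0.252208878352981
"++++---++",-0.681143230652524
"++++--+--",-0.504390327013091
"++++--+-+",-0.953846392891805
"++++--++-",0.752356058977354
"++++--+++",0.263108636160168
"++++-+---",-0.758205768597071
"++++-+--+",-1.24764394111355
"++++-+-+-",0.453031697515477
"++++-+-++",-0.0398457330624059
"++++-++",-0.315262690367949
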