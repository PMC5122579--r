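sweep_id,spike_time_s,amplitude_mV
1,0,1.22591522913
1,0.0333333333333,0.304419659288
1,0.0666666666667,0.0253518437582
1,0.1,-0.048202397348
1,0.133333333333,0.175584574759
1,0.166666666667,0.0590288833066
1,0.2,0.769981061018
1,0.233333333333,0.31647371888
1,0.266666666667,0.196636201031
1,0.3,0.221388478072
1,0.333333333333,0.283090228811
1,0.366666666667,0.309807216891
1,0.4,0.200731242444
1,0.433333333333,0.140063033766
1,0.466666666667,0.437268487187
1,0.5,0.00324236393351
1,0.533333333333,0.230181874109
1,0.566666666667,0.372822053832
1,0.6,0.852383647756
1,0.633333333333,0.032783382961
1,0.666666666667,0.80983050576
1,0.7,0.605153720459
1,0.733333333333,0.011801854575
1,0.766666666667,0.561685907876
1,0.8,0.459116716631
1,0.833333333333,0.435275347558
1,0.866666666667,0.116845558929
1,0.9,-0.0458515193553
1,0.933333333333,0.034477505008
1,0.966666666667,0.065649953747
2,0,0.628201674929
2,0.0333333333333,1.28168193219
2,0.0666666666667,0.257349685908
2,0.1,0.345090038547
2,0.133333333333,0.0116675150313
2,0.166666666667,-0.0636854644785
2,0.2,0.0373438761099
2,0.233333333333,0.0858744594054
2,0.266666666667,0.198877427348
2,0.3,0.0695488533281
2,0.333333333333,0.376727003237
2,0.366666666667,-0.0206336392073
2,0.4,0.177692429961
2,0.433333333333,0.0236635003817
2,0.466666666667,0.128805452943
2,0.5,-0.0357180442632
2,0.533333333333,-0.00764818465718
2,0.566666666667,0.273525510644
2,0.6,0.398585714844
2,0.633333333333,0.000202727295942
2,0.666666666667,0.0793987593194
2,0.7,0.588951928102
2,0.733333333333,-0.0389916771288
2,0.766666666667,0.621667683566
2,0.8,0.155893782414
2,0.833333333333,0.00729185049442
2,0.866666666667,0.0766100778142
2,0.9,-0.0417012384123
2,0.933333333333,0.147588205771
2,0.966666666667,-0.0270658947858
3,0,1.4605035825
3,0.0333333333333,0.472527427369
3,0.0666666666667,0.177328959253
3,0.1,0.584139008275
3,0.133333333333,1.14351408412
3,0.166666666667,0.422582063005
3,0.2,0.401786005043
3,0.233333333333,-0.0502675356879
3,0.266666666667,0.608267614412
3,0.3,-0.0318352192325
3,0.333333333333,0.0242305372281
3,0.366666666667,0.836198921789
3,0.4,0.0819019698614
3,0.433333333333,0.184577021136
3,0.466666666667,0.287679660082
3,0.5,0.702530134994
3,0.533333333333,0.251603974151
3,0.566666666667,0.129772494773
3,0.6,0.609355834899
3,0.633333333333,0.152437882657
3,0.666666666667,-0.0236246151888
3,0.7,-0.0212038584667
3,0.733333333333,0.091174420812
3,0.766666666667,0.212477232235
3,0.8,0.272394051679
3,0.833333333333,0.384939332751
3,0.866666666667,0.0994016992001
3,0.9,0.833625231457
3,0.933333333333,0.220294734889
3,0.966666666667,0.0020215441041
4,0,1.53269447351
4,0.0333333333333,0.47444805803
4,0.0666666666667,0.503811285756
4,0.1,-0.00318269629989
4,0.133333333333,0.273318900381
4,0.166666666667,-0.0314390241399
4,0.2,-0.0448514795454
4,0.233333333333,0.182825824674
4,0.266666666667,0.259080487075
4,0.3,0.0603666723242
4,0.333333333333,0.00733687543065
4,0.366666666667,0.163994282614
4,0.4,0.0541944139448
4,0.433333333333,-0.103661807144
4,0.466666666667,-0.0713487239376
4,0.5,0.0554849842234
4,0.533333333333,0.304195685846
4,0.566666666667,-0.0116166891565
4,0.6,0.0315697059465
4,0.633333333333,0.232647905509
4,0.666666666667,0.529766497308
4,0.7,-0.102344430865
4,0.733333333333,-0.00362696507002
4,0.766666666667,0.198729969995
4,0.8,0.224611043161
4,0.833333333333,-0.0729802695792
4,0.866666666667,0.248735548183
4,0.9,0.354154466527
4,0.933333333333,0.189803388197
4,0.966666666667,-0.0566499236901
5,0,0.669397351768
5,0.0333333333333,0.687758405116
5,0.0666666666667,0.0278545378135
5,0.1,0.893007706531
5,0.133333333333,0.021050864512
5,0.166666666667,0.340349941932
5,0.2,0.0185601270519
5,0.233333333333,-0.0258901661066
5,0.266666666667,-0.0702442842666
5,0.3,0.120916686171
5,0.333333333333,-0.0167870931571
5,0.366666666667,0.0654192873622
5,0.4,0.0480237338526
5,0.433333333333,-0.036035980577
5,0.466666666667,0.00620726943115
5,0.5,0.0216771800741
5,0.533333333333,0.0136400468404
5,0.566666666667,0.293041815596
5,0.6,0.0582613654246
5,0.633333333333,0.187246681514
5,0.666666666667,0.516954655334
5,0.7,-0.0934944335927
5,0.733333333333,0.0428677891915
5,0.766666666667,0.25177877903
5,0.8,0.0469968637143
5,0.833333333333,0.0733047268654
5,0.866666666667,0.0758327881282
5,0.9,0.0992606367072
5,0.933333333333,0.149132402424
5,0.966666666667,-0.000141143352899
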