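# synthetic Clarke-electrode trace: 1 uM Ero1p, 10 mM DTT injected at 100 s
# generated by opfkin::generate_trace(), Gaussian noise sd 1 uM, seed 2026
time_s,o2_uM
      0,258.521
      5, 256.92
     10,258.139
     15,257.915
     20,257.333
     25,255.484
     30,257.265
     35, 256.98
     40,258.114
     45,257.526
     50,257.592
     55, 257.27
     60,257.779
     65,257.774
     70,255.453
     75,259.347
     80,258.616
     85,258.218
     90,257.195
     95, 258.69
    100,257.671
    105,254.896
    110,249.655
    115,248.574
    120,243.292
    125,241.362
    130,237.468
    135, 232.15
    140,229.164
    145,226.741
    150,221.053
    155,218.383
    160,214.663
    165,212.019
    170,208.702
    175,206.583
    180,202.974
    185,198.513
    190,197.068
    195,192.813
    200,189.687
    205,188.888
    210,184.229
    215,183.121
    220,179.417
    225,179.161
    230,176.001
    235,172.486
    240, 171.34
    245,168.671
    250,164.829
    255,163.598
    260,160.727
    265,160.008
    270,156.863
    275,155.272
    280,152.308
    285,150.669
    290,149.894
    295,146.934
    300,146.007
    305,144.572
    310,142.503
    315,140.748
    320,137.681
    325,137.558
    330,134.483
    335,135.925
    340,132.295
    345,132.007
    350,130.974
    355,129.089
    360,129.094
    365,125.595
    370,125.613
    375,122.951
    380,124.841
    385,122.223
    390, 120.04
    395,120.046
    400, 117.01
    405,118.606
    410,114.901
    415,113.484
    420,113.997
    425,113.937
    430,112.136
    435,110.471
    440,111.514
    445,111.883
    450,106.663
    455,109.269
    460,106.516
    465,107.188
    470,103.619
    475,104.438
    480,103.016
    485,102.779
    490,101.504
    495,102.282
    500,102.477
    505,100.132
    510,99.7798
    515,98.2942
    520,99.8158
    525,98.8113
    530,96.1299
    535,98.6347
    540,95.4582
    545,95.0631
    550,94.1447
    555,93.9379
    560, 94.311
    565,94.7322
    570,93.0411
    575,93.1178
    580,92.6118
    585,93.6519
    590,94.3686
    595,90.6208
    600,93.2161
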