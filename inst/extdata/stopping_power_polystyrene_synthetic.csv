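"energy_MeV","L_MeV_per_cm"
0.001,131.741
0.00116591,117.265
0.00135936,104.403
0.00158489,92.974
0.00184785,82.8195
0.00215443,73.797
0.00251189,65.7804
0.00292864,58.6574
0.00341455,52.3286
0.00398107,46.7053
0.00464159,41.7089
0.0054117,37.2695
0.00630957,33.325
0.00735642,29.8202
0.00857696,26.7062
0.01,23.9393
0.0116591,21.4808
0.0135936,19.2965
0.0158489,17.3556
0.0184785,15.6311
0.0215443,14.0989
0.0251189,12.7375
0.0292864,11.5278
0.0341455,10.453
0.0398107,9.49807
0.0464159,8.64956
0.054117,7.89564
0.0630957,7.22577
0.0735642,6.63057
0.0857696,6.10173
0.1,5.63185
0.116591,5.21434
0.135936,4.84339
0.158489,4.51378
0.184785,4.22092
0.215443,3.96071
0.251189,3.72951
0.292864,3.52408
0.341455,3.34156
0.398107,3.17938
0.464159,3.03528
0.54117,2.90725
0.630957,2.79349
0.735642,2.69241
0.857696,2.6026
1,2.5228
1.16591,2.4519
1.35936,2.3889
1.58489,2.33293
1.84785,2.28319
2.15443,2.239
2.51189,2.19974
2.92864,2.16485
3.41455,2.13385
3.98107,2.10631
4.64159,2.08184
5.4117,2.0601
6.30957,2.04078
7.35642,2.02361
8.57696,2.00836
10,1.99481
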