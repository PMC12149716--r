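"field_side_cm","Pwall","Pwall_u","Pscint","Pscint_u"
0.6,1.00009,0.1,1.003,0.1
0.8,1.00004,0.1,1.00273,0.1
1,0.99999,0.1,1.00251,0.1
1.5,0.99988,0.1,1.00213,0.1
2,0.99979,0.1,1.00185,0.1
3,0.99968,0.1,1.00147,0.1
4,0.99961,0.1,1.00119,0.1
5,0.99957,0.1,1.00098,0.1
6,0.99954,0.1,1.00081,0.1
8,0.99951,0.1,1.00053,0.1
10,0.99951,0.1,1.00032,0.1
20,0.9995,0.1,0.99966,0.1
30,0.9995,0.1,0.99927,0.1
40,0.9995,0.1,0.999,0.1
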