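# state: S1
# treatment: NH3
# provenance: synthetic seed=2718
6531 -0.58286099999999996
6531.1000000000004 -0.31770100000000001
6531.1999999999998 0.83600099999999999
6531.3000000000002 0.90032400000000001
6531.3999999999996 0.16430800000000001
6531.5 0.13552900000000001
6531.6000000000004 1.14523
6531.6999999999998 -0.447932
6531.8000000000002 0.031322900000000001
6531.8999999999996 -0.039784300000000002
6532 0.029889099999999998
6532.1000000000004 -0.569577
6532.1999999999998 -0.19988
6532.3000000000002 0.786053
6532.3999999999996 0.35151399999999999
6532.5 -0.033533500000000001
6532.6000000000004 0.136098
6532.6999999999998 -0.405584
6532.8000000000002 -0.74138199999999999
6532.8999999999996 -0.040642400000000002
6533 0.0030108600000000002
6533.1000000000004 -0.58560999999999996
6533.1999999999998 0.92398199999999997
6533.3000000000002 0.035302
6533.3999999999996 0.71825600000000001
6533.5 0.75813699999999995
6533.6000000000004 -0.34199000000000002
6533.6999999999998 -0.92991500000000005
6533.8000000000002 0.28481400000000001
6533.8999999999996 -0.109333
6534 0.69124300000000005
6534.1000000000004 0.77127599999999996
6534.1999999999998 0.246452
6534.3000000000002 0.057597299999999997
6534.3999999999996 0.44285200000000002
6534.5 -0.040674500000000002
6534.6000000000004 -0.29300999999999999
6534.6999999999998 -0.0045757100000000002
6534.8000000000002 0.93045699999999998
6534.8999999999996 0.49427500000000002
6535 -0.28992099999999998
6535.1000000000004 -1.2567900000000001
6535.1999999999998 0.38392100000000001
6535.3000000000002 -0.29616599999999998
6535.3999999999996 0.95242499999999997
6535.5 -0.24024999999999999
6535.6000000000004 1.1340600000000001
6535.6999999999998 -0.80664400000000003
6535.8000000000002 -0.048269600000000003
6535.8999999999996 -0.61171500000000001
6536 0.228209
6536.1000000000004 0.017124299999999999
6536.1999999999998 0.38979200000000003
6536.3000000000002 0.41273799999999999
6536.3999999999996 -0.107312
6536.5 0.0336954
6536.6000000000004 -0.43815100000000001
6536.6999999999998 0.67172500000000002
6536.8000000000002 -0.53875499999999998
6536.8999999999996 -0.077143400000000001
6537 -0.016813100000000001
6537.1000000000004 0.37307200000000001
6537.1999999999998 -0.165961
6537.3000000000002 0.68176899999999996
6537.3999999999996 0.272509
6537.5 0.42294100000000001
6537.6000000000004 0.32499299999999998
6537.6999999999998 0.133828
6537.8000000000002 -0.035090000000000003
6537.8999999999996 -0.76918600000000004
6538 0.39828400000000003
6538.1000000000004 0.044548999999999998
6538.1999999999998 0.15785299999999999
6538.3000000000002 0.97607600000000005
6538.3999999999996 -1.2707900000000001
6538.5 -0.14773900000000001
6538.6000000000004 0.43424800000000002
6538.6999999999998 0.38938899999999999
6538.8000000000002 0.61847200000000002
6538.8999999999996 0.53191500000000003
6539 1.6562300000000001
6539.1000000000004 0.62268199999999996
6539.1999999999998 0.50864200000000004
6539.3000000000002 0.46979300000000002
6539.3999999999996 2.5932900000000001
6539.5 1.87947
6539.6000000000004 1.82246
6539.6999999999998 2.5142899999999999
6539.8000000000002 3.9822700000000002
6539.8999999999996 4.4717099999999999
6540 3.2025000000000001
6540.1000000000004 4.2621799999999999
6540.1999999999998 6.3073300000000003
6540.3000000000002 6.6913999999999998
6540.3999999999996 6.2955199999999998
6540.5 7.2187799999999998
6540.6000000000004 7.8671100000000003
6540.6999999999998 9.0677299999999992
6540.8000000000002 9.6993899999999993
6540.8999999999996 10.171799999999999
6541 11.8505
6541.1000000000004 11.007999999999999
6541.1999999999998 12.670199999999999
6541.3000000000002 12.2461
6541.3999999999996 12.099500000000001
6541.5 11.2507
6541.6000000000004 12.7301
6541.6999999999998 11.3018
6541.8000000000002 11.714399999999999
6541.8999999999996 9.4674800000000001
6542 11.515599999999999
6542.1000000000004 10.638999999999999
6542.1999999999998 10.465
6542.3000000000002 9.7481399999999994
6542.3999999999996 9.1671499999999995
6542.5 7.8948099999999997
6542.6000000000004 9.11571
6542.6999999999998 8.5271100000000004
6542.8000000000002 8.2361699999999995
6542.8999999999996 8.9634499999999999
6543 7.1944499999999998
6543.1000000000004 7.4422300000000003
6543.1999999999998 8.0041600000000006
6543.3000000000002 6.8287399999999998
6543.3999999999996 6.5208599999999999
6543.5 6.0028199999999998
6543.6000000000004 5.9510300000000003
6543.6999999999998 8.0665399999999998
6543.8000000000002 6.4886900000000001
6543.8999999999996 7.3686699999999998
6544 7.6402000000000001
6544.1000000000004 7.8723999999999998
6544.1999999999998 7.9253200000000001
6544.3000000000002 7.6761699999999999
6544.3999999999996 8.5707900000000006
6544.5 9.9130299999999991
6544.6000000000004 10.203799999999999
6544.6999999999998 10.730600000000001
6544.8000000000002 11.130000000000001
6544.8999999999996 11.4373
6545 12.457599999999999
6545.1000000000004 13.0114
6545.1999999999998 14.362
6545.3000000000002 14.5107
6545.3999999999996 16.046600000000002
6545.5 16.5837
6545.6000000000004 17.026199999999999
6545.6999999999998 17.7422
6545.8000000000002 18.105599999999999
6545.8999999999996 19.983799999999999
6546 20.651800000000001
6546.1000000000004 20.948699999999999
6546.1999999999998 23.039999999999999
6546.3000000000002 23.378699999999998
6546.3999999999996 23.662800000000001
6546.5 24.555199999999999
6546.6000000000004 25.4939
6546.6999999999998 27.419499999999999
6546.8000000000002 28.464700000000001
6546.8999999999996 28.9619
6547 30.215199999999999
6547.1000000000004 30.8277
6547.1999999999998 31.995100000000001
6547.3000000000002 32.908099999999997
6547.3999999999996 34.013300000000001
6547.5 34.795000000000002
6547.6000000000004 36.033499999999997
6547.6999999999998 37.036499999999997
6547.8000000000002 37.8673
6547.8999999999996 38.7438
6548 39.819400000000002
6548.1000000000004 40.546799999999998
6548.1999999999998 40.7971
6548.3000000000002 41.756399999999999
6548.3999999999996 42.784799999999997
6548.5 44.224200000000003
6548.6000000000004 45.2988
6548.6999999999998 44.504800000000003
6548.8000000000002 47.453899999999997
6548.8999999999996 47.498899999999999
6549 47.880400000000002
6549.1000000000004 48.1325
6549.1999999999998 48.655700000000003
6549.3000000000002 49.348100000000002
6549.3999999999996 50.801400000000001
6549.5 50.7179
6549.6000000000004 52.4666
6549.6999999999998 51.485799999999998
6549.8000000000002 50.766399999999997
6549.8999999999996 53.594900000000003
6550 53.155999999999999
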