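# state: S2
# treatment: NH3
# provenance: synthetic seed=2718
6531 0.54881400000000002
6531.1000000000004 0.086662500000000003
6531.1999999999998 1.28549
6531.3000000000002 0.027988699999999998
6531.3999999999996 0.20427300000000001
6531.5 -0.56357000000000002
6531.6000000000004 0.89989300000000005
6531.6999999999998 0.44966400000000001
6531.8000000000002 0.160943
6531.8999999999996 -0.39775700000000003
6532 0.76827800000000002
6532.1000000000004 0.090275099999999997
6532.1999999999998 0.79050500000000001
6532.3000000000002 0.44140800000000002
6532.3999999999996 0.214416
6532.5 0.424396
6532.6000000000004 0.76162799999999997
6532.6999999999998 0.90787799999999996
6532.8000000000002 0.54075600000000001
6532.8999999999996 0.020829
6533 -0.32103500000000001
6533.1000000000004 -0.75675099999999995
6533.1999999999998 -0.76541599999999999
6533.3000000000002 -1.38687
6533.3999999999996 -0.70632600000000001
6533.5 0.59797999999999996
6533.6000000000004 0.86642699999999995
6533.6999999999998 -0.908833
6533.8000000000002 -0.58291099999999996
6533.8999999999996 -0.487786
6534 1.14307
6534.1000000000004 -0.73496700000000004
6534.1999999999998 0.17044000000000001
6534.3000000000002 0.27426299999999998
6534.3999999999996 -0.53452900000000003
6534.5 -0.28804999999999997
6534.6000000000004 -0.19247400000000001
6534.6999999999998 -0.215526
6534.8000000000002 -0.64626300000000003
6534.8999999999996 -0.14727399999999999
6535 0.080730399999999994
6535.1000000000004 0.93410400000000005
6535.1999999999998 0.81587299999999996
6535.3000000000002 0.29480699999999999
6535.3999999999996 0.82568900000000001
6535.5 0.28920800000000002
6535.6000000000004 -0.73967300000000002
6535.6999999999998 1.4250799999999999
6535.8000000000002 -0.024840000000000001
6535.8999999999996 -0.033627499999999998
6536 -0.43406
6536.1000000000004 -0.40276299999999998
6536.1999999999998 0.49561899999999998
6536.3000000000002 -0.97985900000000004
6536.3999999999996 -0.045514499999999999
6536.5 -0.55513699999999999
6536.6000000000004 0.43776500000000002
6536.6999999999998 0.935863
6536.8000000000002 0.26191799999999998
6536.8999999999996 1.0439000000000001
6537 0.22134799999999999
6537.1000000000004 0.11765100000000001
6537.1999999999998 0.0708617
6537.3000000000002 -0.37823299999999999
6537.3999999999996 0.41391
6537.5 -0.065993800000000005
6537.6000000000004 -0.33949600000000002
6537.6999999999998 0.34649799999999997
6537.8000000000002 -0.016176800000000002
6537.8999999999996 1.3044100000000001
6538 0.18939300000000001
6538.1000000000004 -0.90520400000000001
6538.1999999999998 -1.0855699999999999
6538.3000000000002 0.614869
6538.3999999999996 0.71727200000000002
6538.5 0.0248647
6538.6000000000004 -0.58087
6538.6999999999998 1.0852999999999999
6538.8000000000002 0.30624800000000002
6538.8999999999996 1.2523500000000001
6539 0.96352400000000005
6539.1000000000004 1.2785
6539.1999999999998 2.8496899999999998
6539.3000000000002 1.47628
6539.3999999999996 3.3882099999999999
6539.5 4.3592399999999998
6539.6000000000004 3.5408599999999999
6539.6999999999998 5.88931
6539.8000000000002 4.9466900000000003
6539.8999999999996 6.2115
6540 6.3690199999999999
6540.1000000000004 5.45085
6540.1999999999998 6.13985
6540.3000000000002 7.0918200000000002
6540.3999999999996 7.15639
6540.5 6.9049399999999999
6540.6000000000004 9.17103
6540.6999999999998 10.093
6540.8000000000002 10.9726
6540.8999999999996 11.1465
6541 12.421099999999999
6541.1000000000004 11.3668
6541.1999999999998 12.8085
6541.3000000000002 12.0558
6541.3999999999996 12.381
6541.5 12.1092
6541.6000000000004 11.366899999999999
6541.6999999999998 12.2723
6541.8000000000002 11.852600000000001
6541.8999999999996 10.0997
6542 10.308199999999999
6542.1000000000004 9.3528500000000001
6542.1999999999998 8.5749300000000002
6542.3000000000002 8.2984899999999993
6542.3999999999996 7.3807600000000004
6542.5 6.8533799999999996
6542.6000000000004 5.6155600000000003
6542.6999999999998 6.2340200000000001
6542.8000000000002 5.6385699999999996
6542.8999999999996 4.3104399999999998
6543 5.7519299999999998
6543.1000000000004 5.4379999999999997
6543.1999999999998 5.9111799999999999
6543.3000000000002 5.0421100000000001
6543.3999999999996 4.9124600000000003
6543.5 5.6271199999999997
6543.6000000000004 6.0797499999999998
6543.6999999999998 5.8197900000000002
6543.8000000000002 5.6452099999999996
6543.8999999999996 7.2388300000000001
6544 7.4334499999999997
6544.1000000000004 7.4935200000000002
6544.1999999999998 7.47499
6544.3000000000002 9.1527600000000007
6544.3999999999996 9.2651400000000006
6544.5 9.4218600000000006
6544.6000000000004 10.211
6544.6999999999998 10.9566
6544.8000000000002 11.068099999999999
6544.8999999999996 11.633100000000001
6545 12.952
6545.1000000000004 12.4625
6545.1999999999998 13.790800000000001
6545.3000000000002 14.972200000000001
6545.3999999999996 14.307600000000001
6545.5 16.977799999999998
6545.6000000000004 17.397200000000002
6545.6999999999998 16.851500000000001
6545.8000000000002 18.2254
6545.8999999999996 18.694800000000001
6546 20.099699999999999
6546.1000000000004 21.148800000000001
6546.1999999999998 21.9633
6546.3000000000002 23.273700000000002
6546.3999999999996 24.0855
6546.5 26.4055
6546.6000000000004 25.171199999999999
6546.6999999999998 26.369700000000002
6546.8000000000002 28.397500000000001
6546.8999999999996 29.192900000000002
6547 30.885100000000001
6547.1000000000004 31.320499999999999
6547.1999999999998 31.798500000000001
6547.3000000000002 33.072400000000002
6547.3999999999996 33.944400000000002
6547.5 34.647399999999998
6547.6000000000004 35.198
6547.6999999999998 36.867800000000003
6547.8000000000002 37.253799999999998
6547.8999999999996 37.640099999999997
6548 39.104500000000002
6548.1000000000004 39.813200000000002
6548.1999999999998 41.585999999999999
6548.3000000000002 42.209400000000002
6548.3999999999996 42.8065
6548.5 43.7834
6548.6000000000004 44.409799999999997
6548.6999999999998 45.3992
6548.8000000000002 46.373199999999997
6548.8999999999996 46.5976
6549 47.2333
6549.1000000000004 48.415199999999999
6549.1999999999998 48.513399999999997
6549.3000000000002 49.579999999999998
6549.3999999999996 49.531999999999996
6549.5 50.356200000000001
6549.6000000000004 51.209899999999998
6549.6999999999998 50.911799999999999
6549.8000000000002 52.421199999999999
6549.8999999999996 51.771799999999999
6550 52.194499999999998
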