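# state: S1
# treatment: native
# provenance: synthetic seed=2718
6531 0.27284999999999998
6531.1000000000004 -0.65451700000000002
6531.1999999999998 0.387098
6531.3000000000002 -0.34626499999999999
6531.3999999999996 -0.40514699999999998
6531.5 -0.34107399999999999
6531.6000000000004 0.57459099999999996
6531.6999999999998 0.39557999999999999
6531.8000000000002 0.99053800000000003
6531.8999999999996 -0.0049781000000000001
6532 1.09108
6532.1000000000004 -0.28572900000000001
6532.1999999999998 -0.0146152
6532.3000000000002 -0.32807900000000001
6532.3999999999996 -0.32555299999999998
6532.5 -1.12382
6532.6000000000004 0.239423
6532.6999999999998 0.248611
6532.8000000000002 -0.121222
6532.8999999999996 -0.062616000000000005
6533 0.79340200000000005
6533.1000000000004 0.17729400000000001
6533.1999999999998 0.13253400000000001
6533.3000000000002 -0.56938599999999995
6533.3999999999996 0.27893600000000002
6533.5 -0.055434400000000002
6533.6000000000004 0.43193799999999999
6533.6999999999998 0.77878199999999997
6533.8000000000002 -0.27220800000000001
6533.8999999999996 0.072812600000000005
6534 -0.40843000000000002
6534.1000000000004 0.038501199999999999
6534.1999999999998 0.55953799999999998
6534.3000000000002 -0.34115499999999999
6534.3999999999996 -0.15454100000000001
6534.5 -0.250444
6534.6000000000004 0.36891400000000002
6534.6999999999998 -0.065584699999999996
6534.8000000000002 0.66151499999999996
6534.8999999999996 0.364033
6535 0.048385499999999998
6535.1000000000004 -0.85836199999999996
6535.1999999999998 0.418186
6535.3000000000002 -0.107817
6535.3999999999996 -0.82489699999999999
6535.5 0.68726699999999996
6535.6000000000004 -0.19389200000000001
6535.6999999999998 0.37007400000000001
6535.8000000000002 -0.210953
6535.8999999999996 -0.76302400000000004
6536 0.30348599999999998
6536.1000000000004 0.53853300000000004
6536.1999999999998 -0.019235499999999999
6536.3000000000002 0.63484700000000005
6536.3999999999996 -0.87505999999999995
6536.5 -0.718032
6536.6000000000004 -0.47006500000000001
6536.6999999999998 0.92875300000000005
6536.8000000000002 0.677006
6536.8999999999996 -0.123108
6537 -1.71715
6537.1000000000004 -0.44441199999999997
6537.1999999999998 -0.18016199999999999
6537.3000000000002 0.49846000000000001
6537.3999999999996 0.071668800000000005
6537.5 -0.38633200000000001
6537.6000000000004 0.35765200000000003
6537.6999999999998 0.21567900000000001
6537.8000000000002 0.014094600000000001
6537.8999999999996 -1.1367499999999999
6538 1.0355000000000001
6538.1000000000004 -0.108666
6538.1999999999998 0.107519
6538.3000000000002 0.449909
6538.3999999999996 -1.24644
6538.5 -0.63388299999999997
6538.6000000000004 -0.52913100000000002
6538.6999999999998 0.12857399999999999
6538.8000000000002 0.40138000000000001
6538.8999999999996 0.025886599999999999
6539 -1.08988
6539.1000000000004 0.53409600000000002
6539.1999999999998 0.66823500000000002
6539.3000000000002 1.7220299999999999
6539.3999999999996 1.2067099999999999
6539.5 1.28508
6539.6000000000004 2.2753299999999999
6539.6999999999998 3.1174200000000001
6539.8000000000002 3.0232700000000001
6539.8999999999996 2.7830699999999999
6540 4.1385300000000003
6540.1000000000004 3.6801599999999999
6540.1999999999998 6.0669599999999999
6540.3000000000002 6.4765600000000001
6540.3999999999996 5.7426300000000001
6540.5 7.0404
6540.6000000000004 7.2122599999999997
6540.6999999999998 9.1167999999999996
6540.8000000000002 9.7974700000000006
6540.8999999999996 9.4962499999999999
6541 10.2918
6541.1000000000004 10.455500000000001
6541.1999999999998 11.074299999999999
6541.3000000000002 11.539
6541.3999999999996 12.6691
6541.5 12.252800000000001
6541.6000000000004 11.0672
6541.6999999999998 11.5116
6541.8000000000002 11.186199999999999
6541.8999999999996 10.511699999999999
6542 11.432499999999999
6542.1000000000004 9.5179600000000004
6542.1999999999998 10.4557
6542.3000000000002 10.6259
6542.3999999999996 9.2475199999999997
6542.5 9.1801200000000005
6542.6000000000004 10.283799999999999
6542.6999999999998 9.0365900000000003
6542.8000000000002 7.70425
6542.8999999999996 8.3391999999999999
6543 7.2390600000000003
6543.1000000000004 7.1733900000000004
6543.1999999999998 6.6410299999999998
6543.3000000000002 6.5762499999999999
6543.3999999999996 7.0692000000000004
6543.5 6.8766299999999996
6543.6000000000004 6.8822299999999998
6543.6999999999998 6.5321999999999996
6543.8000000000002 7.5164900000000001
6543.8999999999996 6.8920199999999996
6544 7.7367699999999999
6544.1000000000004 7.5735400000000004
6544.1999999999998 7.5581899999999997
6544.3000000000002 9.1224799999999995
6544.3999999999996 8.6190999999999995
6544.5 9.6734500000000008
6544.6000000000004 9.9421700000000008
6544.6999999999998 11.482100000000001
6544.8000000000002 10.454499999999999
6544.8999999999996 13.2872
6545 12.0848
6545.1000000000004 13.5146
6545.1999999999998 12.929
6545.3000000000002 15.0076
6545.3999999999996 14.9186
6545.5 16.911200000000001
6545.6000000000004 16.635400000000001
6545.6999999999998 16.828499999999998
6545.8000000000002 17.684699999999999
6545.8999999999996 19.354900000000001
6546 20.437899999999999
6546.1000000000004 22.026900000000001
6546.1999999999998 21.5228
6546.3000000000002 23.170000000000002
6546.3999999999996 23.637499999999999
6546.5 24.837900000000001
6546.6000000000004 25.9572
6546.6999999999998 27.384399999999999
6546.8000000000002 27.720600000000001
6546.8999999999996 28.873200000000001
6547 30.196200000000001
6547.1000000000004 31.769500000000001
6547.1999999999998 31.1493
6547.3000000000002 33.122999999999998
6547.3999999999996 33.672400000000003
6547.5 35.340400000000002
6547.6000000000004 35.644599999999997
6547.6999999999998 36.177999999999997
6547.8000000000002 37.179099999999998
6547.8999999999996 38.703299999999999
6548 39.808399999999999
6548.1000000000004 40.630299999999998
6548.1999999999998 42.014000000000003
6548.3000000000002 41.925800000000002
6548.3999999999996 43.479900000000001
6548.5 44.170999999999999
6548.6000000000004 44.368699999999997
6548.6999999999998 45.003
6548.8000000000002 45.485999999999997
6548.8999999999996 46.937800000000003
6549 47.544499999999999
6549.1000000000004 47.538699999999999
6549.1999999999998 49.991900000000001
6549.3000000000002 50.484499999999997
6549.3999999999996 50.859699999999997
6549.5 50.391599999999997
6549.6000000000004 51.484900000000003
6549.6999999999998 50.801499999999997
6549.8000000000002 51.921500000000002
6549.8999999999996 51.820500000000003
6550 53.7179
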