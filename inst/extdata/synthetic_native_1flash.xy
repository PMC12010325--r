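# state: S2
# treatment: native
# provenance: synthetic seed=2718
6531 0.32572400000000001
6531.1000000000004 0.048964599999999997
6531.1999999999998 0.67535999999999996
6531.3000000000002 -0.25745600000000002
6531.3999999999996 0.26358700000000002
6531.5 0.62658800000000003
6531.6000000000004 0.65840100000000001
6531.6999999999998 -0.26452100000000001
6531.8000000000002 -0.36674200000000001
6531.8999999999996 -0.44196200000000002
6532 0.449013
6532.1000000000004 1.0804499999999999
6532.1999999999998 0.439135
6532.3000000000002 -0.387654
6532.3999999999996 -0.17095299999999999
6532.5 0.75881500000000002
6532.6000000000004 0.424624
6532.6999999999998 -0.0265671
6532.8000000000002 0.58371300000000004
6532.8999999999996 0.40174100000000001
6533 -0.085400100000000007
6533.1000000000004 0.56586700000000001
6533.1999999999998 0.30095499999999997
6533.3000000000002 0.27153100000000002
6533.3999999999996 0.15528900000000001
6533.5 -0.357792
6533.6000000000004 -0.991699
6533.6999999999998 0.61131000000000002
6533.8000000000002 -0.104767
6533.8999999999996 0.068378099999999997
6534 -0.37974000000000002
6534.1000000000004 -1.5061199999999999
6534.1999999999998 0.54977600000000004
6534.3000000000002 0.39993000000000001
6534.3999999999996 -0.462038
6534.5 -0.130607
6534.6000000000004 0.042838800000000003
6534.6999999999998 0.74881600000000004
6534.8000000000002 -0.077270900000000003
6534.8999999999996 0.13461799999999999
6535 0.44969199999999998
6535.1000000000004 -0.54185300000000003
6535.1999999999998 -0.31087199999999998
6535.3000000000002 -0.0306097
6535.3999999999996 -0.47382800000000003
6535.5 -0.063894800000000002
6535.6000000000004 0.54424300000000003
6535.6999999999998 0.0061230599999999996
6535.8000000000002 -0.62536199999999997
6535.8999999999996 0.058735799999999998
6536 0.41985600000000001
6536.1000000000004 -0.54928500000000002
6536.1999999999998 -0.44528099999999998
6536.3000000000002 0.83677500000000005
6536.3999999999996 -0.11042299999999999
6536.5 0.603047
6536.6000000000004 0.24945800000000001
6536.6999999999998 0.63170599999999999
6536.8000000000002 1.4398500000000001
6536.8999999999996 0.81888700000000003
6537 0.33603499999999997
6537.1000000000004 0.218301
6537.1999999999998 0.035472400000000001
6537.3000000000002 -1.06341
6537.3999999999996 -0.92844400000000005
6537.5 0.90322400000000003
6537.6000000000004 0.44061699999999998
6537.6999999999998 0.45341399999999998
6537.8000000000002 -0.33568799999999999
6537.8999999999996 0.83580299999999996
6538 0.15423400000000001
6538.1000000000004 -0.0077380699999999997
6538.1999999999998 0.41088999999999998
6538.3000000000002 0.29072700000000001
6538.3999999999996 0.60653199999999996
6538.5 0.043281
6538.6000000000004 0.59497800000000001
6538.6999999999998 0.71406499999999995
6538.8000000000002 0.15953999999999999
6538.8999999999996 0.58417600000000003
6539 0.85503799999999996
6539.1000000000004 2.0804100000000001
6539.1999999999998 1.38914
6539.3000000000002 1.5166299999999999
6539.3999999999996 2.2942200000000001
6539.5 2.2734299999999998
6539.6000000000004 3.9371900000000002
6539.6999999999998 4.2413699999999999
6539.8000000000002 4.5196100000000001
6539.8999999999996 4.3646099999999999
6540 5.7650100000000002
6540.1000000000004 7.1910400000000001
6540.1999999999998 6.9134799999999998
6540.3000000000002 7.9664900000000003
6540.3999999999996 7.38361
6540.5 9.7617100000000008
6540.6000000000004 8.8941499999999998
6540.6999999999998 10.196300000000001
6540.8000000000002 11.344200000000001
6540.8999999999996 12.344799999999999
6541 12.117699999999999
6541.1000000000004 12.3254
6541.1999999999998 12.0388
6541.3000000000002 13.401400000000001
6541.3999999999996 10.346
6541.5 12.3988
6541.6000000000004 11.011200000000001
6541.6999999999998 10.6218
6541.8000000000002 11.0824
6541.8999999999996 9.7158200000000008
6542 9.9155499999999996
6542.1000000000004 8.6957599999999999
6542.1999999999998 9.8673199999999994
6542.3000000000002 8.4941099999999992
6542.3999999999996 8.6551500000000008
6542.5 8.8874499999999994
6542.6000000000004 8.1494999999999997
6542.6999999999998 6.8867200000000004
6542.8000000000002 7.2705599999999997
6542.8999999999996 6.79915
6543 5.9740599999999997
6543.1000000000004 5.8193700000000002
6543.1999999999998 6.1633500000000003
6543.3000000000002 6.5376899999999996
6543.3999999999996 5.5254599999999998
6543.5 4.8014599999999996
6543.6000000000004 4.8500500000000004
6543.6999999999998 6.7137799999999999
6543.8000000000002 5.9860100000000003
6543.8999999999996 7.1703700000000001
6544 7.0131800000000002
6544.1000000000004 6.88028
6544.1999999999998 7.86327
6544.3000000000002 8.3954500000000003
6544.3999999999996 8.6913
6544.5 10.395
6544.6000000000004 10.661300000000001
6544.6999999999998 10.898
6544.8000000000002 12.0997
6544.8999999999996 12.0246
6545 13.033799999999999
6545.1000000000004 12.6599
6545.1999999999998 13.6167
6545.3000000000002 13.6652
6545.3999999999996 15.6465
6545.5 15.5938
6545.6000000000004 16.415099999999999
6545.6999999999998 18.456199999999999
6545.8000000000002 18.634899999999998
6545.8999999999996 19.247800000000002
6546 19.590499999999999
6546.1000000000004 21.048300000000001
6546.1999999999998 22.498899999999999
6546.3000000000002 23.456700000000001
6546.3999999999996 23.847799999999999
6546.5 25.3035
6546.6000000000004 26.4099
6546.6999999999998 26.864599999999999
6546.8000000000002 27.5364
6546.8999999999996 28.953600000000002
6547 29.318000000000001
6547.1000000000004 29.779900000000001
6547.1999999999998 32.097000000000001
6547.3000000000002 32.967799999999997
6547.3999999999996 33.810400000000001
6547.5 35.101199999999999
6547.6000000000004 35.502200000000002
6547.6999999999998 36.770400000000002
6547.8000000000002 37.639600000000002
6547.8999999999996 39.343899999999998
6548 39.582000000000001
6548.1000000000004 40.863500000000002
6548.1999999999998 41.194600000000001
6548.3000000000002 41.1815
6548.3999999999996 42.160200000000003
6548.5 43.6023
6548.6000000000004 45.052199999999999
6548.6999999999998 44.398400000000002
6548.8000000000002 46.448099999999997
6548.8999999999996 46.568199999999997
6549 48.2637
6549.1000000000004 48.203299999999999
6549.1999999999998 48.7575
6549.3000000000002 49.407200000000003
6549.3999999999996 49.413699999999999
6549.5 50.4741
6549.6000000000004 50.641800000000003
6549.6999999999998 50.9636
6549.8000000000002 52.020099999999999
6549.8999999999996 53.089100000000002
6550 52.640599999999999
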