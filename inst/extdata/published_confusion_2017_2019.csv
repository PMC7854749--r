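year,map_class,rice,maize,soybean,other
2017,rice,868,101,9,20
2017,maize,15,1783,65,441
2017,soybean,17,126,2210,469
2017,other,44,81,180,1660
2018,rice,1206,11,1,39
2018,maize,9,2241,67,667
2018,soybean,3,121,2197,864
2018,other,46,86,131,2974
2019,rice,1092,57,3,16
2019,maize,5,2380,39,419
2019,soybean,6,111,2282,324
2019,other,53,229,203,3821
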