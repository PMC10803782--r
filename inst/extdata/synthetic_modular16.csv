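n1,n2,n3,n4,n5,n6,n7,n8,n9,n10,n11,n12,n13,n14,n15,n16
0.0000000000000000,0.0000000000000000,0.7148536934982985,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.3679018202237785,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.2968464067671448
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.2050496120937169,0.8852210368495435,0.0000000000000000,0.9826594137120992,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000
0.1103351002093405,0.5712338974699378,0.0000000000000000,0.5000250923912972,0.9250458909664303,0.3367135401349515,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.3275060220621526,0.0000000000000000,0.0000000000000000,0.6532182488590479
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.8784290472976863,0.0000000000000000,0.0000000000000000,0.0000000000000000
0.0000000000000000,0.0000000000000000,0.1233005786780268,0.1352304990869015,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.3282740695867687,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.9793343034107238,0.0000000000000000
0.0000000000000000,0.6189515469595790,0.3110496187582612,0.0000000000000000,0.8867535982280970,0.0000000000000000,0.4656905676238239,0.1709963905159384,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.3199476010631770,0.0000000000000000,0.0000000000000000
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.8692578205373138,0.1362958252429962,0.3192741151433438,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000
0.5397982858121395,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.7853494421578944,0.4037828147411346,0.0498921528924257,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.3864540117792785,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.4969034281093627,0.9010704779066145
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.4882548945024610,0.0000000000000000,0.3324459905270487,0.0000000000000000,0.0000000000000000,0.3069656202569604,0.0930746719241142,0.0000000000000000
0.0000000000000000,0.0000000000000000,0.9457391626201570,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.9907957932446152
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.4790773070417345,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0897779711522162,0.0000000000000000,0.9306048862636089,0.0000000000000000,0.0000000000000000,0.4303332213312387
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.4533034141641110,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0186874116770923,0.8672286630608141,0.7570556025020778,0.4837681415956467,0.0000000000000000,0.1078112544491887,0.2117736581712961,0.3937769222538918
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.1873567115981132,0.0000000000000000,0.3394850837066770,0.7317075997125357,0.6029684972018003,0.4445695278700441,0.3921784569974989,0.0000000000000000,0.0000000000000000,0.0000000000000000
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0296633755788207,0.3152607968077064,0.1453999725636095,0.0603855899535120,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.1419088954571635
0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.1357424193993211,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0000000000000000,0.0325174834579229,0.0000000000000000,0.1588467748370022,0.0000000000000000,0.9305007462389767,0.0000000000000000
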