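"pattern","kappa"
"XOOOO",-0.5553
"XXOOO",-0.4488
"XOXOO",-0.0835
"XXXOO",-0.026
"XOOXO",0.3055
"XXOXO",0.439
"XOXXO",0.8784
"XXXXO",0.3771
"XOOOX",-1.2881
"XXOOX",-1.1216
"XOXOX",-0.7005
"XXXOX",-0.8939
"XOOXX",-0.3055
"XXOXX",-0.3144
"XOXXX",0.1571
"OXOOOO",-0.547
"OXXOOO",-0.2959
"OXOXOO",0.0216
"OXXXOO",0.5
"OXOOXO",0.372
"OXXOXO",0.8313
"OXOXXO",1.1687
"OXXXXO",1.6034
"OXOOOX",-1.2501
"OXXOOX",-0.8313
"OXOXOX",-0.5
"OXXXOX",-0.0432
"OXOOXX",-0.1687
"OXXOXX",0.2959
"OXOXXX",0.6108
"OXXXXX",0.8931
"OOXOOOO",-0.5466
"OOXXOOO",-0.2661
"OOXOXOO",0.0385
"OOXXXOO",0.6481
"OOXOOXO",0.3804
"OOXXOXO",0.9345
"OOXOXXO",1.2373
"OOXXXXO",1.9169
"OOXOOOX",-1.2466
"OOXXOOX",-0.7627
"OOXOXOX",-0.458
"OOXXXOX",0.1872
"OOXOOXX",-0.1443
"OOXXOXX",0.4629
"OOXOXXX",0.7323
"OOXXXXX",1.3291
"OOOXOOOO",-0.5466
"OOOXXOOO",-0.2632
"OOOXOXOO",0.0398
"OOOXXXOO",0.6781
"OOOXOOXO",0.3809
"OOOXXOXO",0.9524
"OOOXOXXO",1.247
"OOOXXXXO",2
"OOOXOOOX",-1.2464
"OOOXXOOX",-0.753
"OOOXOXOX",-0.4533
"OOOXXXOX",0.2441
"OOOXOOXX",-0.1422
"OOOXXOXX",0.5
"OOOXOXXX",0.7559
"OOOXXXXX",1.4649
"OOOOXOOOO",-0.5466
"OOOOXXOOO",-0.2631
"OOOOXOXOO",0.0398
"OOOOXXXOO",0.6812
"OOOOXOOXO",0.3809
"OOOOXXOXO",0.9538
"OOOOXOXXO",1.2476
"OOOOXXXXO",2.014
"OOOOXOOOX",-1.2464
"OOOOXXOOX",-0.7524
"OOOOXOXOX",-0.453
"OOOOXXXOX",0.2522
"OOOOXOOXX",-0.1421
"OOOOXXOXX",0.5044
"OOOOXOXXX",0.7582
"OOOOXXXXX",1.4962
"OOOOOXOOOO",-0.5466
"OOOOOXXOOO",-0.2631
"OOOOOXOXOO",0.0398
"OOOOOXXXOO",0.6813
"OOOOOXOOXO",0.3809
"OOOOOXXOXO",0.9539
"OOOOOXOXXO",1.2477
"OOOOOXXXXO",2.015
"OOOOOXOOOX",-1.2464
"OOOOOXXOOX",-0.7523
"OOOOOXOXOX",-0.453
"OOOOOXXXOX",0.2527
"OOOOOXOOXX",-0.1421
"OOOOOXXOXX",0.5046
"OOOOOXOXXX",0.7583
"OOOOOXXXXX",1.5
"OOOOOOXOOOO",-0.5466
"OOOOOOXXOOO",-0.2631
"OOOOOOXOXOO",0.0399
"OOOOOOXXXOO",0.6813
"OOOOOOXOOXO",0.3809
"OOOOOOXXOXO",0.9539
"OOOOOOXOXXO",1.2477
"OOOOOOXXXXO",2.0151
"OOOOOOXOOOX",-1.2464
"OOOOOOXXOOX",-0.7523
"OOOOOOXOXOX",-0.453
"OOOOOOXXXOX",0.2527
"OOOOOOXOOXX",-0.1422
"OOOOOOXXOXX",0.5046
"OOOOOOXOXXX",0.7583
"OOOOOOXXXXX",1.5002
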