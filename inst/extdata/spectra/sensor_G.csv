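wavelength_nm,value
340,6.56272e-06
345,1.19767e-05
350,2.15183e-05
355,3.8062e-05
360,6.62811e-05
365,0.000113632
370,0.000191791
375,0.000318689
380,0.000521341
385,0.000839635
390,0.00133129
395,0.00207812
400,0.0031936
405,0.00483177
410,0.00719689
415,0.0105535
420,0.0152358
425,0.0216545
430,0.0303001
435,0.0417401
440,0.056608
445,0.0755815
450,0.0993501
455,0.128569
460,0.163801
465,0.205452
470,0.253699
475,0.30842
480,0.36913
485,0.434942
490,0.504542
495,0.576205
500,0.647845
505,0.717099
510,0.781451
515,0.838375
520,0.885502
525,0.920778
530,0.942617
535,0.950015
540,0.942628
545,0.920801
550,0.88554
555,0.838432
560,0.781533
565,0.717214
570,0.648005
575,0.576425
580,0.504842
585,0.435349
590,0.369677
595,0.309149
600,0.254666
605,0.206723
610,0.165462
615,0.130724
620,0.102127
625,0.0791352
630,0.0611237
635,0.0474386
640,0.0374414
645,0.0305421
650,0.0262201
655,0.0240351
660,0.023629
665,0.0247216
670,0.0271022
675,0.0306186
680,0.0351651
685,0.040671
690,0.047089
695,0.054385
700,0.0625298
705,0.0714916
710,0.0812294
715,0.0916891
720,0.1028
725,0.11447
730,0.12659
735,0.139029
740,0.151635
745,0.16424
750,0.176663
755,0.18871
760,0.200184
765,0.210887
770,0.220624
775,0.229214
780,0.23649
785,0.242308
790,0.246552
795,0.249133
800,0.25
805,0.249133
810,0.246552
815,0.242308
820,0.23649
825,0.229214
830,0.220624
835,0.210887
840,0.200184
845,0.18871
850,0.176662
855,0.164239
860,0.151633
865,0.139025
870,0.126584
875,0.114458
880,0.102778
885,0.0916511
890,0.0811631
895,0.0713779
900,0.0623381
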