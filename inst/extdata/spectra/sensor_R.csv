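wavelength_nm,value
340,5.07316e-08
345,9.58085e-08
350,1.78718e-07
355,3.29284e-07
360,5.99253e-07
365,1.07718e-06
370,1.91252e-06
375,3.35399e-06
380,5.80973e-06
385,9.94005e-06
390,1.67981e-05
395,2.80394e-05
400,4.62291e-05
405,7.52837e-05
410,0.000121095
415,0.000192392
420,0.000301917
425,0.00046798
430,0.000716481
435,0.00108348
440,0.00161836
445,0.00238763
450,0.00347935
455,0.00500803
460,0.00711991
465,0.00999817
470,0.0138677
475,0.0189989
480,0.0257093
485,0.0343629
490,0.0453657
495,0.0591568
500,0.0761939
505,0.0969336
510,0.121806
515,0.151182
520,0.18534
525,0.224429
530,0.268429
535,0.317116
540,0.370039
545,0.426498
550,0.485543
555,0.545985
560,0.606426
565,0.665302
570,0.720954
575,0.771695
580,0.815901
585,0.852096
590,0.879034
595,0.895775
600,0.90174
605,0.89675
610,0.88104
615,0.855243
620,0.820359
625,0.777694
630,0.728792
635,0.67535
640,0.619129
645,0.561875
650,0.505238
655,0.450711
660,0.399579
665,0.352892
670,0.311446
675,0.27579
680,0.246233
685,0.222872
690,0.205623
695,0.19425
700,0.188401
705,0.187636
710,0.191459
715,0.199334
720,0.210709
725,0.225024
730,0.241719
735,0.260243
740,0.280059
745,0.300638
750,0.321471
755,0.342065
760,0.36195
765,0.38068
770,0.39784
775,0.413053
780,0.425984
785,0.436347
790,0.443914
795,0.448515
800,0.450046
805,0.448468
810,0.44381
815,0.436165
820,0.425688
825,0.412588
830,0.397126
835,0.379598
840,0.360332
845,0.339678
850,0.317992
855,0.29563
860,0.272939
865,0.250245
870,0.227851
875,0.206025
880,0.185001
885,0.164972
890,0.146094
895,0.12848
900,0.112208
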