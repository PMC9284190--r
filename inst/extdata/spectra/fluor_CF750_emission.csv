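wavelength_nm,value
340,2.38741e-54
345,3.88763e-53
350,6.13191e-52
355,9.36823e-51
360,1.38634e-49
365,1.98717e-48
370,2.759e-47
375,3.71038e-46
380,4.83322e-45
385,6.09826e-44
390,7.45294e-43
395,8.82266e-42
400,1.01163e-40
405,1.12357e-39
410,1.20872e-38
415,1.25951e-37
420,1.27125e-36
425,1.24283e-35
430,1.17691e-34
435,1.07951e-33
440,9.59093e-33
445,8.25366e-32
450,6.87992e-31
455,5.55484e-30
460,4.34422e-29
465,3.29081e-28
470,2.4146e-27
475,1.71608e-26
480,1.18136e-25
485,7.87733e-25
490,5.08776e-24
495,3.18292e-23
500,1.92875e-22
505,1.13208e-21
510,6.43621e-21
515,3.54433e-20
520,1.89056e-19
525,9.7678e-19
530,4.88827e-18
535,2.36954e-17
540,1.11256e-16
545,5.05985e-16
550,2.22895e-15
555,9.51077e-15
560,3.93081e-14
565,1.57362e-13
570,6.10194e-13
575,2.29186e-12
580,8.33795e-12
585,2.9382e-11
590,1.0029e-10
595,3.31575e-10
600,1.06184e-09
605,3.29371e-09
610,9.89613e-09
615,2.88002e-08
620,8.11854e-08
625,2.21672e-07
630,5.86267e-07
635,1.50187e-06
640,3.72665e-06
645,8.9569e-06
650,2.0852e-05
655,4.70207e-05
660,0.000102703
665,0.000217283
670,0.000445267
675,0.000883826
680,0.00169928
685,0.00316456
690,0.0057084
695,0.00997393
700,0.0168799
705,0.0276709
710,0.0439369
715,0.0675751
720,0.100669
725,0.145263
730,0.203033
735,0.274871
740,0.360448
745,0.457833
750,0.563279
755,0.671261
760,0.774837
765,0.866325
770,0.938216
775,0.984183
780,1
785,0.984183
790,0.938216
795,0.866325
800,0.774837
805,0.671261
810,0.563279
815,0.457833
820,0.360448
825,0.274871
830,0.203033
835,0.145263
840,0.100669
845,0.0675751
850,0.0439369
855,0.0276709
860,0.0168799
865,0.00997393
870,0.0057084
875,0.00316456
880,0.00169928
885,0.000883826
890,0.000445267
895,0.000217283
900,0.000102703
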