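wavelength_nm,value
340,2.48912e-39
345,9.72275e-38
350,3.51578e-36
355,1.17691e-34
360,3.64716e-33
365,1.0463e-31
370,2.77874e-30
375,6.83169e-29
380,1.55489e-27
385,3.27611e-26
390,6.39011e-25
395,1.15384e-23
400,1.92875e-22
405,2.98466e-21
410,4.27565e-20
415,5.67022e-19
420,6.96125e-18
425,7.91159e-17
430,8.32397e-16
435,8.10749e-15
440,7.31025e-14
445,6.10194e-13
450,4.71512e-12
455,3.37293e-11
460,2.23363e-10
465,1.36932e-09
470,7.77121e-09
475,4.08284e-08
480,1.98575e-07
485,8.94081e-07
490,3.72665e-06
495,1.43797e-05
500,5.13655e-05
505,0.000169857
510,0.000519976
515,0.00147358
520,0.00386592
525,0.00938906
530,0.0211097
535,0.0439369
540,0.084658
545,0.151007
550,0.249352
555,0.381171
560,0.539408
565,0.706648
570,0.856997
575,0.962154
580,1
585,0.962154
590,0.856997
595,0.706648
600,0.539408
605,0.381171
610,0.249352
615,0.151007
620,0.084658
625,0.0439369
630,0.0211097
635,0.00938906
640,0.00386592
645,0.00147358
650,0.000519976
655,0.000169857
660,5.13655e-05
665,1.43797e-05
670,3.72665e-06
675,8.94081e-07
680,1.98575e-07
685,4.08284e-08
690,7.77121e-09
695,1.36932e-09
700,2.23363e-10
705,3.37293e-11
710,4.71512e-12
715,6.10194e-13
720,7.31025e-14
725,8.10749e-15
730,8.32397e-16
735,7.91159e-17
740,6.96125e-18
745,5.67022e-19
750,4.27565e-20
755,2.98466e-21
760,1.92875e-22
765,1.15384e-23
770,6.39011e-25
775,3.27611e-26
780,1.55489e-27
785,6.83169e-29
790,2.77874e-30
795,1.0463e-31
800,3.64716e-33
805,1.17691e-34
810,3.51578e-36
815,9.72275e-38
820,2.48912e-39
825,5.8992e-41
830,1.29428e-42
835,2.62879e-44
840,4.94277e-46
845,8.60352e-48
850,1.38634e-49
855,2.06802e-51
860,2.85581e-53
865,3.65084e-55
870,4.32062e-57
875,4.73358e-59
880,4.80089e-61
885,4.50759e-63
890,3.91792e-65
895,3.15252e-67
900,2.34827e-69
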