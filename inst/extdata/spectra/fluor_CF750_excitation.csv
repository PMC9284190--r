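wavelength_nm,value
340,3.74548e-116
345,2.17828e-113
350,1.17276e-110
355,5.84514e-108
360,2.69693e-105
365,1.15195e-102
370,4.555e-100
375,1.66737e-97
380,5.65022e-95
385,1.77251e-92
390,5.14756e-90
395,1.3839e-87
400,3.44426e-85
405,7.93555e-83
410,1.69258e-80
415,3.34202e-78
420,6.10885e-76
425,1.03371e-73
430,1.61931e-71
435,2.34827e-69
440,3.15252e-67
445,3.91792e-65
450,4.50759e-63
455,4.80089e-61
460,4.73358e-59
465,4.32062e-57
470,3.65084e-55
475,2.85581e-53
480,2.06802e-51
485,1.38634e-49
490,8.60352e-48
495,4.94277e-46
500,2.62879e-44
505,1.29428e-42
510,5.8992e-41
515,2.48912e-39
520,9.72275e-38
525,3.51578e-36
530,1.17691e-34
535,3.64716e-33
540,1.0463e-31
545,2.77874e-30
550,6.83169e-29
555,1.55489e-27
560,3.27611e-26
565,6.39011e-25
570,1.15384e-23
575,1.92875e-22
580,2.98466e-21
585,4.27565e-20
590,5.67022e-19
595,6.96125e-18
600,7.91159e-17
605,8.32397e-16
610,8.10749e-15
615,7.31025e-14
620,6.10194e-13
625,4.71512e-12
630,3.37293e-11
635,2.23363e-10
640,1.36932e-09
645,7.77121e-09
650,4.08284e-08
655,1.98575e-07
660,8.94081e-07
665,3.72665e-06
670,1.43797e-05
675,5.13655e-05
680,0.000169857
685,0.000519976
690,0.00147358
695,0.00386592
700,0.00938906
705,0.0211097
710,0.0439369
715,0.084658
720,0.151007
725,0.249352
730,0.381171
735,0.539408
740,0.706648
745,0.856997
750,0.962154
755,1
760,0.962154
765,0.856997
770,0.706648
775,0.539408
780,0.381171
785,0.249352
790,0.151007
795,0.084658
800,0.0439369
805,0.0211097
810,0.00938906
815,0.00386592
820,0.00147358
825,0.000519976
830,0.000169857
835,5.13655e-05
840,1.43797e-05
845,3.72665e-06
850,8.94081e-07
855,1.98575e-07
860,4.08284e-08
865,7.77121e-09
870,1.36932e-09
875,2.23363e-10
880,3.37293e-11
885,4.71512e-12
890,6.10194e-13
895,7.31025e-14
900,8.10749e-15
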