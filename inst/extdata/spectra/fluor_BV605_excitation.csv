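wavelength_nm,value
340,0.00147358
345,0.00386592
350,0.00938906
355,0.0211097
360,0.0439369
365,0.084658
370,0.151007
375,0.249352
380,0.381171
385,0.539408
390,0.706648
395,0.856997
400,0.962154
405,1
410,0.962154
415,0.856997
420,0.706648
425,0.539408
430,0.381171
435,0.249352
440,0.151007
445,0.084658
450,0.0439369
455,0.0211097
460,0.00938906
465,0.00386592
470,0.00147358
475,0.000519976
480,0.000169857
485,5.13655e-05
490,1.43797e-05
495,3.72665e-06
500,8.94081e-07
505,1.98575e-07
510,4.08284e-08
515,7.77121e-09
520,1.36932e-09
525,2.23363e-10
530,3.37293e-11
535,4.71512e-12
540,6.10194e-13
545,7.31025e-14
550,8.10749e-15
555,8.32397e-16
560,7.91159e-17
565,6.96125e-18
570,5.67022e-19
575,4.27565e-20
580,2.98466e-21
585,1.92875e-22
590,1.15384e-23
595,6.39011e-25
600,3.27611e-26
605,1.55489e-27
610,6.83169e-29
615,2.77874e-30
620,1.0463e-31
625,3.64716e-33
630,1.17691e-34
635,3.51578e-36
640,9.72275e-38
645,2.48912e-39
650,5.8992e-41
655,1.29428e-42
660,2.62879e-44
665,4.94277e-46
670,8.60352e-48
675,1.38634e-49
680,2.06802e-51
685,2.85581e-53
690,3.65084e-55
695,4.32062e-57
700,4.73358e-59
705,4.80089e-61
710,4.50759e-63
715,3.91792e-65
720,3.15252e-67
725,2.34827e-69
730,1.61931e-71
735,1.03371e-73
740,6.10885e-76
745,3.34202e-78
750,1.69258e-80
755,7.93555e-83
760,3.44426e-85
765,1.3839e-87
770,5.14756e-90
775,1.77251e-92
780,5.65022e-95
785,1.66737e-97
790,4.555e-100
795,1.15195e-102
800,2.69693e-105
805,5.84514e-108
810,1.17276e-110
815,2.17828e-113
820,3.74548e-116
825,5.96199e-119
830,8.78545e-122
835,1.19847e-124
840,1.51349e-127
845,1.76938e-130
850,1.91493e-133
855,1.91856e-136
860,1.77945e-139
865,1.52787e-142
870,1.21444e-145
875,8.93626e-149
880,6.08731e-152
885,3.8387e-155
890,2.24095e-158
895,1.21108e-161
900,6.05897e-165
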