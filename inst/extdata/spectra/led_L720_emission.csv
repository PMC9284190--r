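wavelength_nm,value
340,5.97186e-194
345,6.72196e-189
350,6.48599e-184
355,5.36477e-179
360,3.80382e-174
365,2.31198e-169
370,1.20459e-164
375,5.38013e-160
380,2.05986e-155
385,6.76049e-151
390,1.90201e-146
395,4.58713e-142
400,9.4834e-138
405,1.68066e-133
410,2.55324e-129
415,3.32505e-125
420,3.71191e-121
425,3.55215e-117
430,2.91393e-113
435,2.04909e-109
440,1.2352e-105
445,6.38276e-102
450,2.82731e-98
455,1.07358e-94
460,3.49451e-91
465,9.75066e-88
470,2.33225e-84
475,4.78203e-81
480,8.40509e-78
485,1.26639e-74
490,1.63563e-71
495,1.81092e-68
500,1.71872e-65
505,1.39832e-62
510,9.7522e-60
515,5.83032e-57
520,2.98797e-54
525,1.31267e-51
530,4.94342e-49
535,1.59586e-46
540,4.41626e-44
545,1.04764e-41
550,2.13039e-39
555,3.71367e-37
560,5.54934e-35
565,7.10842e-33
570,7.80547e-31
575,7.34717e-29
580,5.92836e-27
585,4.10056e-25
590,2.43135e-23
595,1.23579e-21
600,5.38438e-20
605,2.01104e-18
610,6.43875e-17
615,1.76716e-15
620,4.15761e-14
625,8.38507e-13
630,1.44965e-11
635,2.1484e-10
640,2.72936e-09
645,2.97235e-08
650,2.77481e-07
655,2.22056e-06
660,1.52329e-05
665,8.95778e-05
670,0.000451555
675,0.00195126
680,0.00722795
685,0.0229514
690,0.0624735
695,0.145773
700,0.291577
705,0.499947
710,0.734833
715,0.925864
720,1
725,0.925864
730,0.734833
735,0.499947
740,0.291577
745,0.145773
750,0.0624735
755,0.0229514
760,0.00722795
765,0.00195126
770,0.000451555
775,8.95778e-05
780,1.52329e-05
785,2.22056e-06
790,2.77481e-07
795,2.97235e-08
800,2.72936e-09
805,2.1484e-10
810,1.44965e-11
815,8.38507e-13
820,4.15761e-14
825,1.76716e-15
830,6.43875e-17
835,2.01104e-18
840,5.38438e-20
845,1.23579e-21
850,2.43135e-23
855,4.10056e-25
860,5.92836e-27
865,7.34717e-29
870,7.80547e-31
875,7.10842e-33
880,5.54934e-35
885,3.71367e-37
890,2.13039e-39
895,1.04764e-41
900,4.41626e-44
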