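wavelength_nm,value
340,1.92875e-22
345,5.11442e-21
350,1.21356e-19
355,2.57676e-18
360,4.89587e-17
365,8.32397e-16
370,1.26642e-14
375,1.72412e-13
380,2.10041e-12
385,2.28973e-11
390,2.23363e-10
395,1.94977e-09
400,1.523e-08
405,1.06454e-07
410,6.65836e-07
415,3.72665e-06
420,1.86645e-05
425,8.36483e-05
430,0.000335463
435,0.00120386
440,0.00386592
445,0.011109
450,0.0285655
455,0.0657285
460,0.135335
465,0.249352
470,0.411112
475,0.606531
480,0.800737
485,0.945959
490,1
495,0.945959
500,0.800737
505,0.606531
510,0.411112
515,0.249352
520,0.135335
525,0.0657285
530,0.0285655
535,0.011109
540,0.00386592
545,0.00120386
550,0.000335463
555,8.36483e-05
560,1.86645e-05
565,3.72665e-06
570,6.65836e-07
575,1.06454e-07
580,1.523e-08
585,1.94977e-09
590,2.23363e-10
595,2.28973e-11
600,2.10041e-12
605,1.72412e-13
610,1.26642e-14
615,8.32397e-16
620,4.89587e-17
625,2.57676e-18
630,1.21356e-19
635,5.11442e-21
640,1.92875e-22
645,6.50879e-24
650,1.96548e-25
655,5.31109e-27
660,1.28423e-28
665,2.77874e-30
670,5.38019e-32
675,9.32163e-34
680,1.44521e-35
685,2.00501e-37
690,2.48912e-39
695,2.76516e-41
700,2.74879e-43
705,2.44515e-45
710,1.94633e-47
715,1.38634e-49
720,8.83631e-52
725,5.03983e-54
730,2.57221e-56
735,1.17474e-58
740,4.80089e-61
745,1.75569e-63
750,5.74537e-66
755,1.68242e-68
760,4.40853e-71
765,1.03371e-73
770,2.16895e-76
775,4.07236e-79
780,6.84206e-82
785,1.02866e-84
790,1.3839e-87
795,1.66602e-90
800,1.79474e-93
805,1.73008e-96
810,1.49237e-99
815,1.15195e-102
820,7.95674e-106
825,4.91792e-109
830,2.72003e-112
835,1.3462e-115
840,5.96199e-119
845,2.36275e-122
850,8.37894e-126
855,2.65892e-129
860,7.55036e-133
865,1.91856e-136
870,4.36241e-140
875,8.87612e-144
880,1.61609e-147
885,2.63301e-151
890,3.8387e-155
895,5.00797e-159
900,5.84633e-163
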