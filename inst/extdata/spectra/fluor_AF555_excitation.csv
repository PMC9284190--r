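wavelength_nm,value
340,2.44515e-45
345,2.74879e-43
350,2.76516e-41
355,2.48912e-39
360,2.00501e-37
365,1.44521e-35
370,9.32163e-34
375,5.38019e-32
380,2.77874e-30
385,1.28423e-28
390,5.31109e-27
395,1.96548e-25
400,6.50879e-24
405,1.92875e-22
410,5.11442e-21
415,1.21356e-19
420,2.57676e-18
425,4.89587e-17
430,8.32397e-16
435,1.26642e-14
440,1.72412e-13
445,2.10041e-12
450,2.28973e-11
455,2.23363e-10
460,1.94977e-09
465,1.523e-08
470,1.06454e-07
475,6.65836e-07
480,3.72665e-06
485,1.86645e-05
490,8.36483e-05
495,0.000335463
500,0.00120386
505,0.00386592
510,0.011109
515,0.0285655
520,0.0657285
525,0.135335
530,0.249352
535,0.411112
540,0.606531
545,0.800737
550,0.945959
555,1
560,0.945959
565,0.800737
570,0.606531
575,0.411112
580,0.249352
585,0.135335
590,0.0657285
595,0.0285655
600,0.011109
605,0.00386592
610,0.00120386
615,0.000335463
620,8.36483e-05
625,1.86645e-05
630,3.72665e-06
635,6.65836e-07
640,1.06454e-07
645,1.523e-08
650,1.94977e-09
655,2.23363e-10
660,2.28973e-11
665,2.10041e-12
670,1.72412e-13
675,1.26642e-14
680,8.32397e-16
685,4.89587e-17
690,2.57676e-18
695,1.21356e-19
700,5.11442e-21
705,1.92875e-22
710,6.50879e-24
715,1.96548e-25
720,5.31109e-27
725,1.28423e-28
730,2.77874e-30
735,5.38019e-32
740,9.32163e-34
745,1.44521e-35
750,2.00501e-37
755,2.48912e-39
760,2.76516e-41
765,2.74879e-43
770,2.44515e-45
775,1.94633e-47
780,1.38634e-49
785,8.83631e-52
790,5.03983e-54
795,2.57221e-56
800,1.17474e-58
805,4.80089e-61
810,1.75569e-63
815,5.74537e-66
820,1.68242e-68
825,4.40853e-71
830,1.03371e-73
835,2.16895e-76
840,4.07236e-79
845,6.84206e-82
850,1.02866e-84
855,1.3839e-87
860,1.66602e-90
865,1.79474e-93
870,1.73008e-96
875,1.49237e-99
880,1.15195e-102
885,7.95674e-106
890,4.91792e-109
895,2.72003e-112
900,1.3462e-115
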