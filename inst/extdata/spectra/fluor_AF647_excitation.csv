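wavelength_nm,value
340,1.79474e-93
345,1.66602e-90
350,1.3839e-87
355,1.02866e-84
360,6.84206e-82
365,4.07236e-79
370,2.16895e-76
375,1.03371e-73
380,4.40853e-71
385,1.68242e-68
390,5.74537e-66
395,1.75569e-63
400,4.80089e-61
405,1.17474e-58
410,2.57221e-56
415,5.03983e-54
420,8.83631e-52
425,1.38634e-49
430,1.94633e-47
435,2.44515e-45
440,2.74879e-43
445,2.76516e-41
450,2.48912e-39
455,2.00501e-37
460,1.44521e-35
465,9.32163e-34
470,5.38019e-32
475,2.77874e-30
480,1.28423e-28
485,5.31109e-27
490,1.96548e-25
495,6.50879e-24
500,1.92875e-22
505,5.11442e-21
510,1.21356e-19
515,2.57676e-18
520,4.89587e-17
525,8.32397e-16
530,1.26642e-14
535,1.72412e-13
540,2.10041e-12
545,2.28973e-11
550,2.23363e-10
555,1.94977e-09
560,1.523e-08
565,1.06454e-07
570,6.65836e-07
575,3.72665e-06
580,1.86645e-05
585,8.36483e-05
590,0.000335463
595,0.00120386
600,0.00386592
605,0.011109
610,0.0285655
615,0.0657285
620,0.135335
625,0.249352
630,0.411112
635,0.606531
640,0.800737
645,0.945959
650,1
655,0.945959
660,0.800737
665,0.606531
670,0.411112
675,0.249352
680,0.135335
685,0.0657285
690,0.0285655
695,0.011109
700,0.00386592
705,0.00120386
710,0.000335463
715,8.36483e-05
720,1.86645e-05
725,3.72665e-06
730,6.65836e-07
735,1.06454e-07
740,1.523e-08
745,1.94977e-09
750,2.23363e-10
755,2.28973e-11
760,2.10041e-12
765,1.72412e-13
770,1.26642e-14
775,8.32397e-16
780,4.89587e-17
785,2.57676e-18
790,1.21356e-19
795,5.11442e-21
800,1.92875e-22
805,6.50879e-24
810,1.96548e-25
815,5.31109e-27
820,1.28423e-28
825,2.77874e-30
830,5.38019e-32
835,9.32163e-34
840,1.44521e-35
845,2.00501e-37
850,2.48912e-39
855,2.76516e-41
860,2.74879e-43
865,2.44515e-45
870,1.94633e-47
875,1.38634e-49
880,8.83631e-52
885,5.03983e-54
890,2.57221e-56
895,1.17474e-58
900,4.80089e-61
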