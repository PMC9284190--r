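wavelength_nm,value
340,1.13977e-205
345,1.36721e-198
350,1.23152e-191
355,8.32984e-185
360,4.23078e-178
365,1.61359e-171
370,4.62118e-165
375,9.93807e-159
380,1.60487e-152
385,1.9461e-146
390,1.77207e-140
395,1.21167e-134
400,6.2212e-129
405,2.39858e-123
410,6.94419e-118
415,1.50966e-112
420,2.46447e-107
425,3.02104e-102
430,2.78085e-97
435,1.92215e-92
440,9.9767e-88
445,3.88843e-83
450,1.13802e-78
455,2.501e-74
460,4.1273e-70
465,5.11454e-66
470,4.75922e-62
475,3.32547e-58
480,1.74485e-54
485,6.8747e-51
490,2.03393e-47
495,4.51864e-44
500,7.5382e-41
505,9.44313e-38
510,8.88285e-35
515,6.27448e-32
520,3.32806e-29
525,1.32554e-26
530,3.96445e-24
535,8.90352e-22
540,1.50151e-19
545,1.90145e-17
550,1.80813e-15
555,1.2911e-13
560,6.9228e-12
565,2.78735e-10
570,8.42731e-09
575,1.91326e-07
580,3.26174e-06
585,4.17554e-05
590,0.000401388
595,0.00289737
600,0.0157048
605,0.0639218
610,0.195368
615,0.448381
620,0.772733
625,1
630,0.97176
635,0.709098
640,0.388545
645,0.15987
650,0.0493945
655,0.0114599
660,0.0019965
665,0.000261184
670,2.56574e-05
675,1.89264e-06
680,1.04836e-07
685,4.36056e-09
690,1.36195e-10
695,3.19426e-12
700,5.62558e-14
705,7.43965e-16
710,7.38799e-18
715,5.5092e-20
720,3.08489e-22
725,1.29711e-24
730,4.09549e-27
735,9.71004e-30
740,1.72872e-32
745,2.3111e-35
750,2.32006e-38
755,1.74891e-41
760,9.8998e-45
765,4.20797e-48
770,1.3431e-51
775,3.21907e-55
780,5.79352e-59
785,7.82966e-63
790,7.94568e-67
795,6.05492e-71
800,3.46476e-75
805,1.48877e-79
810,4.80363e-84
815,1.16386e-88
820,2.11748e-93
825,2.89286e-98
830,2.96772e-103
835,2.28616e-108
840,1.32245e-113
845,5.74435e-119
850,1.87366e-124
855,4.58911e-130
860,8.44025e-136
865,1.16566e-141
870,1.20885e-147
875,9.4138e-154
880,5.50485e-160
885,2.41721e-166
890,7.97023e-173
895,1.97341e-179
900,3.66902e-186
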