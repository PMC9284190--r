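wavelength_nm,value
340,8.19489e-06
345,2.11473e-05
350,5.24317e-05
355,0.0001249
360,0.000285862
365,0.00062861
370,0.00132811
375,0.00269596
380,0.00525802
385,0.0098528
390,0.0177388
395,0.0306844
400,0.0509964
405,0.0814309
410,0.12493
415,0.184151
420,0.2608
425,0.354871
430,0.46394
435,0.582748
440,0.70328
445,0.815462
450,0.908464
455,0.972388
460,1
465,0.988072
470,0.938005
475,0.855559
480,0.749762
485,0.631284
490,0.510686
495,0.396928
500,0.296413
505,0.212673
510,0.146607
515,0.0971014
520,0.0617908
525,0.0377791
530,0.0221925
535,0.0125254
540,0.00679207
545,0.00353869
550,0.00177137
555,0.000851935
560,0.000393669
565,0.000174777
570,7.4553e-05
575,3.05545e-05
580,1.20313e-05
585,4.55174e-06
590,1.65452e-06
595,5.77822e-07
600,1.93885e-07
605,6.25062e-08
610,1.93611e-08
615,5.76189e-09
620,1.64751e-09
625,4.52606e-10
630,1.19465e-10
635,3.02962e-11
640,7.38183e-12
645,1.7281e-12
650,3.88688e-13
655,8.39966e-14
660,1.74402e-14
665,3.47911e-15
670,6.66828e-16
675,1.22797e-16
680,2.17265e-17
685,3.69334e-18
690,6.03223e-19
695,9.46596e-20
700,1.42718e-20
705,2.06739e-21
710,2.87736e-22
715,3.84763e-23
720,4.94335e-24
725,6.10207e-25
730,7.23704e-26
735,8.24657e-27
740,9.02847e-28
745,9.49692e-29
750,9.59798e-30
755,9.31977e-31
760,8.69478e-32
765,7.79364e-33
770,6.71197e-34
775,5.55378e-35
780,4.41525e-36
785,3.37248e-37
790,2.47498e-38
795,1.74511e-39
800,1.18223e-40
805,7.69502e-42
810,4.81222e-43
815,2.89141e-44
820,1.66917e-45
825,9.2581e-47
830,4.93368e-48
835,2.52608e-49
840,1.24266e-50
845,5.87335e-52
850,2.66715e-53
855,1.16369e-54
860,4.87815e-56
865,1.96472e-57
870,7.60283e-59
875,2.82669e-60
880,1.00974e-61
885,3.46551e-63
890,1.14276e-64
895,3.62051e-66
900,1.10208e-67
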