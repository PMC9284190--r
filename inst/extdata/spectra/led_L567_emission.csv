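wavelength_nm,value
340,2.16957e-13
345,7.72934e-13
350,2.67683e-12
355,9.0118e-12
360,2.94926e-11
365,9.38265e-11
370,2.90168e-10
375,8.72337e-10
380,2.54936e-09
385,7.24249e-09
390,2.00012e-08
395,5.36953e-08
400,1.40129e-07
405,3.55491e-07
410,8.76682e-07
415,2.10168e-06
420,4.89781e-06
425,1.10956e-05
430,2.44347e-05
435,5.2309e-05
440,0.000108857
445,0.000220216
450,0.000433063
455,0.000827875
460,0.00153847
465,0.00277924
470,0.0048806
475,0.00833167
480,0.0138262
485,0.022304
490,0.0349764
495,0.0533186
500,0.079012
505,0.11382
510,0.159388
515,0.216972
520,0.28712
525,0.369346
530,0.461865
535,0.561446
540,0.663456
545,0.762127
550,0.851047
555,0.923828
560,0.974855
565,1
570,0.997174
575,0.966615
580,0.91085
585,0.834356
590,0.742963
595,0.643124
600,0.541169
605,0.442672
610,0.352
615,0.272091
620,0.204455
625,0.149345
630,0.106047
635,0.0732004
640,0.049118
645,0.0320391
650,0.0203156
655,0.0125225
660,0.0075035
665,0.00437066
670,0.00247481
675,0.00136222
680,0.000728895
685,0.000379135
690,0.000191705
695,9.42288e-05
700,4.50242e-05
705,2.09131e-05
710,9.44285e-06
715,4.14475e-06
720,1.7685e-06
725,7.33538e-07
730,2.95768e-07
735,1.15929e-07
740,4.41716e-08
745,1.63608e-08
750,5.89087e-09
755,2.06188e-09
760,7.01553e-10
765,2.32043e-10
770,7.46081e-11
775,2.33193e-11
780,7.08527e-12
785,2.09271e-12
790,6.00858e-13
795,1.67705e-13
800,4.55021e-14
805,1.20013e-14
810,3.07706e-15
815,7.6693e-16
820,1.85817e-16
825,4.3765e-17
830,1.00203e-17
835,2.2302e-18
840,4.82524e-19
845,1.01486e-19
850,2.07493e-20
855,4.12393e-21
860,7.96766e-22
865,1.49645e-22
870,2.73215e-23
875,4.84906e-24
880,8.36607e-25
885,1.40313e-25
890,2.28762e-26
895,3.62562e-27
900,5.58588e-28
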