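wavelength_nm,value
340,1.09616e-26
345,9.96334e-25
350,7.58805e-23
355,4.84228e-21
360,2.5892e-19
365,1.16004e-17
370,4.35491e-16
375,1.36987e-14
380,3.61055e-13
385,7.97375e-12
390,1.47553e-10
395,2.28784e-09
400,2.97235e-08
405,3.2357e-07
410,2.95143e-06
415,2.25575e-05
420,0.000144459
425,0.000775163
430,0.00348527
435,0.0131303
440,0.0414484
445,0.109632
450,0.242974
455,0.451208
460,0.702085
465,0.915372
470,1
475,0.915372
480,0.702085
485,0.451208
490,0.242974
495,0.109632
500,0.0414484
505,0.0131303
510,0.00348527
515,0.000775163
520,0.000144459
525,2.25575e-05
530,2.95143e-06
535,3.2357e-07
540,2.97235e-08
545,2.28784e-09
550,1.47553e-10
555,7.97375e-12
560,3.61055e-13
565,1.36987e-14
570,4.35491e-16
575,1.16004e-17
580,2.5892e-19
585,4.84228e-21
590,7.58805e-23
595,9.96334e-25
600,1.09616e-26
605,1.01051e-28
610,7.80547e-31
615,5.05189e-33
620,2.7397e-35
625,1.24494e-37
630,4.74009e-40
635,1.51224e-42
640,4.0425e-45
645,9.0547e-48
650,1.69939e-50
655,2.67243e-53
660,3.5214e-56
665,3.88793e-59
670,3.59681e-62
675,2.78811e-65
680,1.81092e-68
685,9.85557e-72
690,4.49427e-75
695,1.71725e-78
700,5.49794e-82
705,1.4749e-85
710,3.31528e-89
715,6.24414e-93
720,9.85418e-97
725,1.30305e-100
730,1.44378e-104
735,1.34039e-108
740,1.0427e-112
745,6.79643e-117
750,3.71191e-121
755,1.69867e-125
760,6.51352e-130
765,2.09275e-134
770,5.63395e-139
775,1.27088e-143
780,2.4021e-148
785,3.80427e-153
790,5.04833e-158
795,5.6133e-163
800,5.22979e-168
805,4.08267e-173
810,2.67055e-178
815,1.46369e-183
820,6.72196e-189
825,2.58664e-194
830,8.3401e-200
835,2.25321e-205
840,5.10065e-211
845,9.67487999999999e-217
850,1.53766e-222
855,2.04772e-228
860,2.28494e-234
865,2.13636e-240
870,1.67366e-246
875,1.09864e-252
880,6.04284e-259
885,2.78497e-265
890,1.07546e-271
895,3.47987e-278
900,9.43465999999999e-285
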