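wavelength_nm,value
340,0.774142
345,0.876341
350,0.953134
355,0.996008
360,1
365,0.96464
370,0.894044
375,0.796124
380,0.681131
385,0.559898
390,0.442197
395,0.335545
400,0.244632
405,0.171358
410,0.115325
415,0.0745713
420,0.0463284
425,0.0276536
430,0.0158593
435,0.00873865
440,0.00462629
445,0.00235315
450,0.00114999
455,0.000539968
460,0.000243596
465,0.000105584
470,4.39701e-05
475,1.75932e-05
480,6.7633e-06
485,2.49805e-06
490,8.86486e-07
495,3.02253e-07
500,9.90145e-08
505,3.11641e-08
510,9.42406e-09
515,2.7381e-09
520,7.64346e-10
525,2.05002e-10
530,5.28269e-11
535,1.30792e-11
540,3.11124e-12
545,7.11074e-13
550,1.56144e-13
555,3.29429e-14
560,6.67772e-15
565,1.30054e-15
570,2.43358e-16
575,4.37518e-17
580,7.55743e-18
585,1.25424e-18
590,1.99994e-19
595,3.06394e-20
600,4.50995e-21
605,6.37811e-22
610,8.66643e-23
615,1.1314e-23
620,1.41913e-24
625,1.71023e-25
630,1.98023e-26
635,2.20295e-27
640,2.35463e-28
645,2.41807e-29
650,2.38584e-30
655,2.26175e-31
660,2.06004e-32
665,1.80274e-33
670,1.51572e-34
675,1.22443e-35
680,9.50339e-37
685,7.0868e-38
690,5.0775e-39
695,3.49525e-40
700,2.31171e-41
705,1.46899e-42
710,8.96873e-44
715,5.26104e-45
720,2.96511e-46
725,1.6056e-47
730,8.35341e-49
735,4.17559e-50
740,2.00539e-51
745,9.25357e-53
750,4.10249e-54
755,1.74749e-55
760,7.1517e-57
765,2.81211e-58
770,1.06239e-59
775,3.85623e-61
780,1.34484e-62
785,4.50616e-64
790,1.45068e-65
795,4.48708e-67
800,1.33347e-68
805,3.80744e-70
810,1.0445e-71
815,2.75306e-73
820,6.97186e-75
825,1.69633e-76
830,3.96552e-78
835,8.90673e-80
840,1.92205e-81
845,3.9851e-83
850,7.93857e-85
855,1.5194e-86
860,2.79404e-88
865,4.93651e-90
870,8.37984e-92
875,1.36672e-93
880,2.14167e-95
885,3.22442e-97
890,4.66424e-99
895,6.48242e-101
900,8.6561e-103
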