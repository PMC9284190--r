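wavelength_nm,value
340,2.70987e-60
345,4.56622e-58
350,6.97835e-56
355,9.67246e-54
360,1.21593e-51
365,1.38634e-49
370,1.43357e-47
375,1.34449e-45
380,1.14363e-43
385,8.82266e-42
390,6.1731e-40
395,3.91737e-38
400,2.25463e-36
405,1.17691e-34
410,5.57187e-33
415,2.39247e-31
420,9.31708e-30
425,3.29081e-28
430,1.05418e-26
435,3.06275e-25
440,8.07049e-24
445,1.92875e-22
450,4.18062e-21
455,8.21851e-20
460,1.46533e-18
465,2.36954e-17
470,3.47522e-16
475,4.62263e-15
480,5.57679e-14
485,6.10194e-13
490,6.05535e-12
495,5.45004e-11
500,4.44886e-10
505,3.29371e-09
510,2.21163e-08
515,1.34687e-07
520,7.43923e-07
525,3.72665e-06
530,1.69316e-05
535,6.97696e-05
540,0.000260749
545,0.000883826
550,0.00271706
555,0.00757568
560,0.0191572
565,0.0439369
570,0.0913938
575,0.172422
580,0.295023
585,0.457833
590,0.644389
595,0.822578
600,0.952345
605,1
610,0.952345
615,0.822578
620,0.644389
625,0.457833
630,0.295023
635,0.172422
640,0.0913938
645,0.0439369
650,0.0191572
655,0.00757568
660,0.00271706
665,0.000883826
670,0.000260749
675,6.97696e-05
680,1.69316e-05
685,3.72665e-06
690,7.43923e-07
695,1.34687e-07
700,2.21163e-08
705,3.29371e-09
710,4.44886e-10
715,5.45004e-11
720,6.05535e-12
725,6.10194e-13
730,5.57679e-14
735,4.62263e-15
740,3.47522e-16
745,2.36954e-17
750,1.46533e-18
755,8.21851e-20
760,4.18062e-21
765,1.92875e-22
770,8.07049e-24
775,3.06275e-25
780,1.05418e-26
785,3.29081e-28
790,9.31708e-30
795,2.39247e-31
800,5.57187e-33
805,1.17691e-34
810,2.25463e-36
815,3.91737e-38
820,6.1731e-40
825,8.82266e-42
830,1.14363e-43
835,1.34449e-45
840,1.43357e-47
845,1.38634e-49
850,1.21593e-51
855,9.67246e-54
860,6.97835e-56
865,4.56622e-58
870,2.70987e-60
875,1.45858e-62
880,7.12032e-65
885,3.15252e-67
890,1.26591e-69
895,4.6104e-72
900,1.52287e-74
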