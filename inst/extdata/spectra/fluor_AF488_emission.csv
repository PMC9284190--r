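wavelength_nm,value
340,9.31708e-30
345,3.29081e-28
350,1.05418e-26
355,3.06275e-25
360,8.07049e-24
365,1.92875e-22
370,4.18062e-21
375,8.21851e-20
380,1.46533e-18
385,2.36954e-17
390,3.47522e-16
395,4.62263e-15
400,5.57679e-14
405,6.10194e-13
410,6.05535e-12
415,5.45004e-11
420,4.44886e-10
425,3.29371e-09
430,2.21163e-08
435,1.34687e-07
440,7.43923e-07
445,3.72665e-06
450,1.69316e-05
455,6.97696e-05
460,0.000260749
465,0.000883826
470,0.00271706
475,0.00757568
480,0.0191572
485,0.0439369
490,0.0913938
495,0.172422
500,0.295023
505,0.457833
510,0.644389
515,0.822578
520,0.952345
525,1
530,0.952345
535,0.822578
540,0.644389
545,0.457833
550,0.295023
555,0.172422
560,0.0913938
565,0.0439369
570,0.0191572
575,0.00757568
580,0.00271706
585,0.000883826
590,0.000260749
595,6.97696e-05
600,1.69316e-05
605,3.72665e-06
610,7.43923e-07
615,1.34687e-07
620,2.21163e-08
625,3.29371e-09
630,4.44886e-10
635,5.45004e-11
640,6.05535e-12
645,6.10194e-13
650,5.57679e-14
655,4.62263e-15
660,3.47522e-16
665,2.36954e-17
670,1.46533e-18
675,8.21851e-20
680,4.18062e-21
685,1.92875e-22
690,8.07049e-24
695,3.06275e-25
700,1.05418e-26
705,3.29081e-28
710,9.31708e-30
715,2.39247e-31
720,5.57187e-33
725,1.17691e-34
730,2.25463e-36
735,3.91737e-38
740,6.1731e-40
745,8.82266e-42
750,1.14363e-43
755,1.34449e-45
760,1.43357e-47
765,1.38634e-49
770,1.21593e-51
775,9.67246e-54
780,6.97835e-56
785,4.56622e-58
790,2.70987e-60
795,1.45858e-62
800,7.12032e-65
805,3.15252e-67
810,1.26591e-69
815,4.6104e-72
820,1.52287e-74
825,4.56219e-77
830,1.23958e-79
835,3.05465e-82
840,6.82713e-85
845,1.3839e-87
850,2.54424e-90
855,4.24228e-93
860,6.41549e-96
865,8.79932e-99
870,1.0946e-101
875,1.23496e-104
880,1.26368e-107
885,1.17276e-110
890,9.87121e-114
895,7.53564e-117
900,5.21745e-120
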