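wavelength_nm,value
340,0
345,0
350,0
355,0
360,0
365,0
370,0
375,0
380,0
385,0
390,0
395,0
400,0
405,0
410,0
415,0.793805
420,0.93
425,0.93
430,0.93
435,0.93
440,0.93
445,0.93
450,0.465
455,0
460,0
465,0
470,0
475,0
480,0
485,0
490,0
495,0
500,0.465
505,0.93
510,0.93
515,0.93
520,0.93
525,0.93
530,0.465
535,0
540,0
545,0
550,0
555,0
560,0
565,0
570,0
575,0
580,0.793805
585,0.93
590,0.93
595,0.93
600,0.93
605,0.93
610,0.793805
615,0
620,0
625,0
630,0
635,0
640,0
645,0
650,0
655,0
660,0.136195
665,0.93
670,0.93
675,0.93
680,0.93
685,0.93
690,0.93
695,0.93
700,0.793805
705,0
710,0
715,0
720,0
725,0
730,0
735,0
740,0
745,0
750,0
755,0
760,0
765,0
770,0
775,0
780,0.793805
785,0.93
790,0.93
795,0.93
800,0.93
805,0.93
810,0.93
815,0.93
820,0.93
825,0.93
830,0.93
835,0.93
840,0.136195
845,0
850,0
855,0
860,0
865,0
870,0
875,0
880,0
885,0
890,0
895,0
900,0
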