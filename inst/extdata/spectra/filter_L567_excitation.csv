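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
415,0
420,0
425,0
430,0
435,0
440,0
445,0
450,0
455,0
460,0
465,0
470,0
475,0
480,0
485,0
490,0
495,0
500,0
505,0
510,0
515,0
520,0
525,0
530,0
535,0
540,0.93
545,0.93
550,0.93
555,0.93
560,0.93
565,0
570,0
575,0
580,0
585,0
590,0
595,0
600,0
605,0
610,0
615,0
620,0
625,0
630,0
635,0
640,0
645,0
650,0
655,0
660,0
665,0
670,0
675,0
680,0
685,0
690,0
695,0
700,0
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
780,0
785,0
790,0
795,0
800,0
805,0
810,0
815,0
820,0
825,0
830,0
835,0
840,0
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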