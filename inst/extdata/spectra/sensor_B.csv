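wavelength_nm,value
340,0.00252147
345,0.00407323
350,0.00644703
355,0.0099981
360,0.0151919
365,0.0226174
370,0.0329922
375,0.0471538
380,0.0660327
385,0.090602
390,0.121802
395,0.160438
400,0.20706
405,0.261831
410,0.324403
415,0.393808
420,0.468405
425,0.545878
430,0.623312
435,0.697354
440,0.764429
445,0.821029
450,0.864005
455,0.890863
460,0.9
465,0.890863
470,0.864005
475,0.821029
480,0.764429
485,0.697354
490,0.623313
495,0.545878
500,0.468406
505,0.393809
510,0.324405
515,0.261834
520,0.207063
525,0.160443
530,0.12181
535,0.0906136
540,0.0660494
545,0.0471777
550,0.0330262
555,0.0226653
560,0.015259
565,0.0100914
570,0.0065759
575,0.00424999
580,0.00276225
585,0.00185504
590,0.00134636
595,0.00111283
600,0.0010751
605,0.00118598
610,0.00142143
615,0.00177394
620,0.00224788
625,0.00285639
630,0.00361938
635,0.00456219
640,0.00571473
645,0.00711084
650,0.00878775
655,0.0107854
660,0.0131458
665,0.0159119
670,0.0191269
675,0.0228324
680,0.0270671
685,0.0318651
690,0.0372541
695,0.043253
700,0.0498704
705,0.0571023
710,0.0649305
715,0.0733209
720,0.0822225
725,0.0915667
730,0.101267
735,0.11122
740,0.121306
745,0.131391
750,0.14133
755,0.150968
760,0.160147
765,0.16871
770,0.176499
775,0.183371
780,0.189192
785,0.193847
790,0.197241
795,0.199307
800,0.2
805,0.199307
810,0.197241
815,0.193847
820,0.189192
825,0.183371
830,0.176499
835,0.16871
840,0.160147
845,0.150968
850,0.14133
855,0.131391
860,0.121306
865,0.11122
870,0.101267
875,0.0915667
880,0.0822225
885,0.0733209
890,0.0649305
895,0.0571023
900,0.0498704
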