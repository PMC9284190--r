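wavelength_nm,value
340,0.00012533
345,0.000826003
350,0.00436078
355,0.0184418
360,0.0624735
365,0.16953
370,0.368511
375,0.641669
380,0.89501
385,1
390,0.89501
395,0.641669
400,0.368511
405,0.16953
410,0.0624735
415,0.0184418
420,0.00436078
425,0.000826003
430,0.00012533
435,1.52329e-05
440,1.48309e-06
445,1.15667e-07
450,7.22611e-09
455,3.61623e-10
460,1.44965e-11
465,4.65508e-13
470,1.19742e-14
475,2.46729e-16
480,4.07239e-18
485,5.38438e-20
490,5.70265e-22
495,4.83809e-24
500,3.28796e-26
505,1.78993e-28
510,7.80547e-31
515,2.72659e-33
520,7.62947e-36
525,1.71012e-38
530,3.07052e-41
535,4.41626e-44
540,5.08807e-47
545,4.69577e-50
550,3.4715e-53
555,2.0558e-56
560,9.7522e-60
565,3.70578e-63
570,1.12801e-66
575,2.75042e-70
580,5.37209e-74
585,8.40509e-78
590,1.05341e-81
595,1.05757e-85
600,8.505e-90
605,5.47894e-94
610,2.82731e-98
615,1.16871e-102
620,3.86987e-107
625,1.02646e-111
630,2.18093e-116
635,3.71191e-121
640,5.06068e-126
645,5.52683e-131
650,4.83503e-136
655,3.38827e-141
660,1.90201e-146
665,8.55269e-152
670,3.08069e-157
675,8.88894e-163
680,2.05451e-168
685,3.80382e-174
690,5.64142e-180
695,6.70213e-186
700,6.37812e-192
705,4.86215e-198
710,2.96906e-204
715,1.45233e-210
720,5.69074e-217
725,1.78619e-223
730,4.49098e-230
735,9.04504e-237
740,1.45927e-243
745,1.88589e-250
750,1.95233e-257
755,1.619e-264
760,1.07546e-271
765,5.72266e-279
770,2.43925e-286
775,8.32859999999999e-294
780,2.27794e-301
785,4.99079e-309
790,8.75893015532929e-317
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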