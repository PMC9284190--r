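wavelength_nm,value
340,7.92635e-73
345,1.20392e-70
350,1.69283e-68
355,2.20353e-66
360,2.6553e-64
365,2.96208e-62
370,3.05894e-60
375,2.92438e-58
380,2.58814e-56
385,2.12046e-54
390,1.60828e-52
395,1.12923e-50
400,7.33998e-49
405,4.41668e-47
410,2.46029e-45
415,1.26872e-43
420,6.05671e-42
425,2.67668e-40
430,1.09508e-38
435,4.14748e-37
440,1.45416e-35
445,4.71987e-34
450,1.4182e-32
455,3.94489e-31
460,1.01583e-29
465,2.42158e-28
470,5.34398e-27
475,1.09174e-25
480,2.06474e-24
485,3.61494e-23
490,5.85902e-22
495,8.79103e-21
500,1.22108e-19
505,1.57013e-18
510,1.86905e-17
515,2.05965e-16
520,2.10114e-15
525,1.9843e-14
530,1.7348e-13
535,1.40404e-12
540,1.05196e-11
545,7.29644e-11
550,4.68502e-10
555,2.78484e-09
560,1.53243e-08
565,7.80637e-08
570,3.68135e-07
575,1.60715e-06
580,6.49522e-06
585,2.43008e-05
590,8.41663e-05
595,0.000269864
600,0.000801016
605,0.00220104
610,0.0055989
615,0.0131846
620,0.0287424
625,0.0580052
630,0.108368
635,0.187424
640,0.300081
645,0.444776
650,0.610286
655,0.775204
660,0.911565
665,0.992314
670,1
675,0.932912
680,0.805696
685,0.644156
690,0.476761
695,0.326663
700,0.207199
705,0.121665
710,0.0661355
715,0.0332807
720,0.0155039
725,0.00668616
730,0.00266933
735,0.00098655
740,0.00033754
745,0.000106911
750,3.13477e-05
755,8.50903e-06
760,2.13818e-06
765,4.97391e-07
770,1.07113e-07
775,2.13538e-08
780,3.94092e-09
785,6.73302e-10
790,1.06491e-10
795,1.55921e-11
800,2.11341e-12
805,2.65189e-13
810,3.08046e-14
815,3.31258e-15
820,3.29766e-16
825,3.03903e-17
830,2.59271e-18
835,2.04768e-19
840,1.49714e-20
845,1.01333e-21
850,6.34931e-23
855,3.68293e-24
860,1.97765e-25
865,9.83098e-27
870,4.5241e-28
875,1.92734e-29
880,7.60105e-31
885,2.7751e-32
890,9.37935e-34
895,2.93465e-35
900,8.50023e-37
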