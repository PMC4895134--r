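wavelength_nm,xbar,ybar,zbar
360,0.0001299,0.000003917,0.0006061
365,0.0002321,0.000006965,0.001086
370,0.0004149,0.00001239,0.001946
375,0.0007416,0.00002202,0.003486
380,0.001368,0.000039,0.006450001
385,0.002236,0.000064,0.01054999
390,0.004243,0.00012,0.02005001
395,0.00765,0.000217,0.03621
400,0.01431,0.000396,0.06785001
405,0.02319,0.00064,0.1102
410,0.04351,0.00121,0.2074
415,0.07763,0.00218,0.3713
420,0.13438,0.004,0.6456
425,0.21477,0.0073,1.0390501
430,0.2839,0.0116,1.3856
435,0.3285,0.01684,1.62296
440,0.34828,0.023,1.74706
445,0.34806,0.0298,1.7826
450,0.3362,0.038,1.77211
455,0.3187,0.048,1.7441
460,0.2908,0.06,1.6692
465,0.2511,0.0739,1.5281
470,0.19536,0.09098,1.28764
475,0.1421,0.1126,1.0419
480,0.09564,0.13902,0.8129501
485,0.05795001,0.1693,0.6162
490,0.03201,0.20802,0.46518
495,0.0147,0.2586,0.3533
500,0.0049,0.323,0.272
505,0.0024,0.4073,0.2123
510,0.0093,0.503,0.1582
515,0.0291,0.6082,0.1117
520,0.06327,0.71,0.07824999
525,0.1096,0.7932,0.05725001
530,0.1655,0.862,0.04216
535,0.2257499,0.9148501,0.02984
540,0.2904,0.954,0.0203
545,0.3597,0.9803,0.0134
550,0.4334499,0.9949501,0.008749999
555,0.5120501,1,0.005749999
560,0.5945,0.995,0.0039
565,0.6784,0.9786,0.002749999
570,0.7621,0.952,0.0021
575,0.8425,0.9154,0.0018
580,0.9163,0.87,0.001650001
585,0.9786,0.8163,0.0014
590,1.0263,0.757,0.0011
595,1.0567,0.6949,0.001
600,1.0622,0.631,0.0008
605,1.0456,0.5668,0.0006
610,1.0026,0.503,0.00034
615,0.9384,0.4412,0.00024
620,0.8544499,0.381,0.00019
625,0.7514,0.321,0.0001
630,0.6424,0.265,0.00004999999
635,0.5419,0.217,0.00003
640,0.4479,0.175,0.00002
645,0.3608,0.1382,0.00001
650,0.2835,0.107,0
655,0.2187,0.0816,0
660,0.1649,0.061,0
665,0.1212,0.04458,0
670,0.0874,0.032,0
675,0.0636,0.0232,0
680,0.04677,0.017,0
685,0.0329,0.01192,0
690,0.0227,0.00821,0
695,0.01584,0.005723,0
700,0.01135916,0.004102,0
705,0.008110916,0.002929,0
710,0.005790346,0.002091,0
715,0.004109457,0.001484,0
720,0.002899327,0.001047,0
725,0.00204919,0.00074,0
730,0.001439971,0.00052,0
735,0.000999949,0.0003611,0
740,0.000690079,0.0002492,0
745,0.000476021,0.0001719,0
750,0.000332301,0.00012,0
755,0.000234826,0.0000848,0
760,0.000166151,0.00006,0
765,0.000117413,0.0000424,0
770,0.000083075,0.00003,0
775,0.000058707,0.0000212,0
780,0.00004151,0.00001499,0
785,0.000029353,0.0000106,0
790,0.000020674,0.0000074657,0
795,0.000014559,0.0000052578,0
800,0.000010254,0.0000037029,0
805,0.000007221,0.0000026078,0
810,0.000005086,0.0000018366,0
815,0.000003582,0.0000012934,0
820,0.000002522,0.00000091093,0
825,0.000001776,0.00000064153,0
830,0.000001251,0.00000045181,0
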