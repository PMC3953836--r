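wavelength_nm,leaf_green
300,0.05
301,0.05
302,0.05
303,0.05
304,0.05
305,0.05
306,0.05
307,0.05
308,0.05
309,0.05
310,0.05
311,0.05
312,0.05
313,0.05
314,0.05
315,0.05
316,0.05
317,0.05
318,0.05
319,0.05
320,0.05
321,0.05
322,0.05
323,0.05
324,0.05
325,0.05
326,0.05
327,0.05
328,0.05
329,0.05
330,0.05
331,0.05
332,0.05
333,0.05
334,0.05
335,0.05
336,0.05
337,0.05
338,0.05
339,0.05
340,0.05
341,0.05
342,0.05
343,0.05
344,0.05
345,0.05
346,0.05
347,0.05
348,0.05
349,0.05
350,0.05
351,0.05
352,0.05
353,0.05
354,0.05
355,0.05
356,0.05
357,0.05
358,0.05
359,0.05
360,0.05
361,0.05
362,0.05
363,0.05
364,0.05
365,0.05
366,0.05
367,0.05
368,0.05
369,0.05
370,0.05
371,0.05
372,0.05
373,0.05
374,0.05
375,0.05
376,0.050001
377,0.050001
378,0.050001
379,0.050001
380,0.050001
381,0.050001
382,0.050001
383,0.050001
384,0.050002
385,0.050002
386,0.050002
387,0.050002
388,0.050003
389,0.050003
390,0.050003
391,0.050004
392,0.050005
393,0.050005
394,0.050006
395,0.050007
396,0.050008
397,0.050009
398,0.05001
399,0.050011
400,0.050012
401,0.050014
402,0.050016
403,0.050018
404,0.05002
405,0.050023
406,0.050025
407,0.050028
408,0.050032
409,0.050036
410,0.05004
411,0.050045
412,0.050051
413,0.050057
414,0.050063
415,0.050071
416,0.050079
417,0.050088
418,0.050098
419,0.050109
420,0.050121
421,0.050135
422,0.05015
423,0.050166
424,0.050184
425,0.050204
426,0.050226
427,0.05025
428,0.050276
429,0.050305
430,0.050336
431,0.050371
432,0.050408
433,0.050449
434,0.050494
435,0.050543
436,0.050596
437,0.050654
438,0.050717
439,0.050785
440,0.05086
441,0.05094
442,0.051027
443,0.051121
444,0.051223
445,0.051333
446,0.051452
447,0.05158
448,0.051718
449,0.051866
450,0.052026
451,0.052197
452,0.052381
453,0.052578
454,0.052789
455,0.053016
456,0.053258
457,0.053516
458,0.053792
459,0.054086
460,0.054399
461,0.054732
462,0.055087
463,0.055464
464,0.055863
465,0.056287
466,0.056736
467,0.057211
468,0.057714
469,0.058244
470,0.058804
471,0.059395
472,0.060016
473,0.060671
474,0.061358
475,0.06208
476,0.062838
477,0.063632
478,0.064463
479,0.065332
480,0.06624
481,0.067188
482,0.068177
483,0.069206
484,0.070278
485,0.071392
486,0.072548
487,0.073748
488,0.074991
489,0.076278
490,0.077608
491,0.078982
492,0.0804
493,0.081861
494,0.083364
495,0.084911
496,0.086499
497,0.088128
498,0.089798
499,0.091507
500,0.093254
501,0.095037
502,0.096856
503,0.098709
504,0.100593
505,0.102508
506,0.10445
507,0.106419
508,0.10841
509,0.110423
510,0.112454
511,0.114501
512,0.11656
513,0.118629
514,0.120705
515,0.122784
516,0.124863
517,0.126938
518,0.129007
519,0.131065
520,0.133108
521,0.135134
522,0.137138
523,0.139116
524,0.141065
525,0.142981
526,0.144859
527,0.146696
528,0.148489
529,0.150233
530,0.151924
531,0.153559
532,0.155135
533,0.156648
534,0.158094
535,0.159471
536,0.160774
537,0.162002
538,0.16315
539,0.164218
540,0.165201
541,0.166098
542,0.166906
543,0.167624
544,0.16825
545,0.168782
546,0.169219
547,0.16956
548,0.169805
549,0.169951
550,0.17
551,0.169952
552,0.169805
553,0.169561
554,0.16922
555,0.168782
556,0.16825
557,0.167625
558,0.166907
559,0.166098
560,0.165202
561,0.164219
562,0.163151
563,0.162003
564,0.160775
565,0.159472
566,0.158096
567,0.15665
568,0.155137
569,0.153562
570,0.151926
571,0.150235
572,0.148491
573,0.146699
574,0.144862
575,0.142984
576,0.141069
577,0.13912
578,0.137143
579,0.135139
580,0.133114
581,0.131071
582,0.129013
583,0.126945
584,0.12487
585,0.122792
586,0.120714
587,0.118639
588,0.116571
589,0.114512
590,0.112467
591,0.110437
592,0.108425
593,0.106435
594,0.104468
595,0.102527
596,0.100614
597,0.098732
598,0.096881
599,0.095064
600,0.093283
601,0.091539
602,0.089833
603,0.088166
604,0.08654
605,0.084955
606,0.083413
607,0.081913
608,0.080457
609,0.079044
610,0.077675
611,0.076351
612,0.07507
613,0.073834
614,0.072642
615,0.071494
616,0.070389
617,0.069327
618,0.068308
619,0.067331
620,0.066395
621,0.0655
622,0.064646
623,0.06383
624,0.063054
625,0.062315
626,0.061613
627,0.060948
628,0.060318
629,0.059722
630,0.05916
631,0.058631
632,0.058134
633,0.057668
634,0.057233
635,0.056827
636,0.05645
637,0.056101
638,0.055779
639,0.055485
640,0.055216
641,0.054974
642,0.054757
643,0.054565
644,0.054397
645,0.054254
646,0.054135
647,0.05404
648,0.053969
649,0.053922
650,0.0539
651,0.053902
652,0.053929
653,0.053981
654,0.05406
655,0.054166
656,0.054299
657,0.054462
658,0.054654
659,0.054878
660,0.055134
661,0.055426
662,0.055753
663,0.056119
664,0.056526
665,0.056977
666,0.057473
667,0.058018
668,0.058616
669,0.059269
670,0.059981
671,0.060756
672,0.061599
673,0.062514
674,0.063505
675,0.064578
676,0.065738
677,0.06699
678,0.068341
679,0.069796
680,0.071361
681,0.073044
682,0.07485
683,0.076786
684,0.078858
685,0.081074
686,0.08344
687,0.085962
688,0.088646
689,0.091498
690,0.094524
691,0.097727
692,0.101111
693,0.10468
694,0.108436
695,0.112379
696,0.116508
697,0.120823
698,0.125319
699,0.129992
700,0.134836
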