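wavelength_nm,illuminant_6500k
300,0.723462
301,0.729193
302,0.73489
303,0.740554
304,0.746183
305,0.751778
306,0.757337
307,0.762861
308,0.768348
309,0.773798
310,0.779211
311,0.784587
312,0.789924
313,0.795223
314,0.800483
315,0.805704
316,0.810885
317,0.816026
318,0.821126
319,0.826186
320,0.831205
321,0.836182
322,0.841118
323,0.846011
324,0.850863
325,0.855672
326,0.860438
327,0.865161
328,0.869841
329,0.874477
330,0.87907
331,0.883619
332,0.888124
333,0.892584
334,0.897001
335,0.901373
336,0.9057
337,0.909982
338,0.914219
339,0.918412
340,0.922559
341,0.926661
342,0.930718
343,0.934729
344,0.938695
345,0.942616
346,0.946491
347,0.95032
348,0.954104
349,0.957842
350,0.961534
351,0.965181
352,0.968782
353,0.972338
354,0.975848
355,0.979312
356,0.982731
357,0.986104
358,0.989432
359,0.992714
360,0.995951
361,0.999143
362,1.002289
363,1.005391
364,1.008447
365,1.011459
366,1.014425
367,1.017347
368,1.020224
369,1.023057
370,1.025845
371,1.028589
372,1.031289
373,1.033945
374,1.036557
375,1.039125
376,1.041649
377,1.044131
378,1.046568
379,1.048963
380,1.051315
381,1.053624
382,1.055891
383,1.058115
384,1.060297
385,1.062437
386,1.064535
387,1.066591
388,1.068606
389,1.070579
390,1.072512
391,1.074403
392,1.076254
393,1.078065
394,1.079835
395,1.081565
396,1.083256
397,1.084906
398,1.086518
399,1.08809
400,1.089624
401,1.091118
402,1.092574
403,1.093993
404,1.095373
405,1.096715
406,1.09802
407,1.099287
408,1.100518
409,1.101711
410,1.102868
411,1.103989
412,1.105074
413,1.106123
414,1.107136
415,1.108114
416,1.109057
417,1.109965
418,1.110839
419,1.111678
420,1.112483
421,1.113254
422,1.113992
423,1.114697
424,1.115368
425,1.116007
426,1.116613
427,1.117186
428,1.117728
429,1.118238
430,1.118716
431,1.119164
432,1.11958
433,1.119965
434,1.12032
435,1.120645
436,1.120939
437,1.121204
438,1.121439
439,1.121646
440,1.121823
441,1.121971
442,1.122091
443,1.122183
444,1.122247
445,1.122283
446,1.122292
447,1.122273
448,1.122228
449,1.122156
450,1.122057
451,1.121932
452,1.121782
453,1.121605
454,1.121403
455,1.121176
456,1.120924
457,1.120647
458,1.120346
459,1.12002
460,1.119671
461,1.119297
462,1.1189
463,1.11848
464,1.118037
465,1.117571
466,1.117083
467,1.116572
468,1.116039
469,1.115484
470,1.114908
471,1.11431
472,1.113691
473,1.113051
474,1.11239
475,1.111709
476,1.111007
477,1.110286
478,1.109545
479,1.108784
480,1.108004
481,1.107204
482,1.106386
483,1.105549
484,1.104693
485,1.103819
486,1.102927
487,1.102018
488,1.10109
489,1.100145
490,1.099183
491,1.098204
492,1.097208
493,1.096195
494,1.095166
495,1.094121
496,1.09306
497,1.091983
498,1.09089
499,1.089782
500,1.088659
501,1.08752
502,1.086367
503,1.085199
504,1.084017
505,1.082821
506,1.08161
507,1.080385
508,1.079147
509,1.077895
510,1.07663
511,1.075352
512,1.074061
513,1.072757
514,1.07144
515,1.070111
516,1.068769
517,1.067416
518,1.06605
519,1.064673
520,1.063284
521,1.061884
522,1.060473
523,1.05905
524,1.057616
525,1.056172
526,1.054717
527,1.053252
528,1.051776
529,1.05029
530,1.048794
531,1.047289
532,1.045773
533,1.044249
534,1.042714
535,1.041171
536,1.039618
537,1.038057
538,1.036487
539,1.034908
540,1.033321
541,1.031725
542,1.030121
543,1.028509
544,1.026889
545,1.025261
546,1.023626
547,1.021983
548,1.020333
549,1.018675
550,1.017011
551,1.015339
552,1.013661
553,1.011975
554,1.010283
555,1.008585
556,1.00688
557,1.005169
558,1.003452
559,1.001729
560,1
561,0.998265
562,0.996525
563,0.994779
564,0.993028
565,0.991271
566,0.989509
567,0.987742
568,0.98597
569,0.984193
570,0.982412
571,0.980626
572,0.978835
573,0.97704
574,0.97524
575,0.973437
576,0.971629
577,0.969817
578,0.968002
579,0.966182
580,0.964359
581,0.962532
582,0.960701
583,0.958868
584,0.95703
585,0.95519
586,0.953346
587,0.9515
588,0.94965
589,0.947797
590,0.945942
591,0.944084
592,0.942223
593,0.94036
594,0.938495
595,0.936627
596,0.934756
597,0.932884
598,0.931009
599,0.929133
600,0.927254
601,0.925374
602,0.923491
603,0.921607
604,0.919722
605,0.917834
606,0.915946
607,0.914055
608,0.912164
609,0.910271
610,0.908377
611,0.906482
612,0.904586
613,0.902688
614,0.90079
615,0.898891
616,0.896991
617,0.895091
618,0.89319
619,0.891288
620,0.889385
621,0.887482
622,0.885579
623,0.883675
624,0.881771
625,0.879867
626,0.877963
627,0.876058
628,0.874154
629,0.872249
630,0.870345
631,0.86844
632,0.866536
633,0.864632
634,0.862728
635,0.860825
636,0.858922
637,0.857019
638,0.855117
639,0.853215
640,0.851314
641,0.849414
642,0.847514
643,0.845615
644,0.843716
645,0.841819
646,0.839922
647,0.838027
648,0.836132
649,0.834238
650,0.832346
651,0.830454
652,0.828563
653,0.826674
654,0.824786
655,0.822899
656,0.821014
657,0.819129
658,0.817246
659,0.815365
660,0.813485
661,0.811607
662,0.80973
663,0.807854
664,0.80598
665,0.804108
666,0.802238
667,0.800369
668,0.798502
669,0.796636
670,0.794773
671,0.792911
672,0.791051
673,0.789193
674,0.787337
675,0.785483
676,0.783631
677,0.781781
678,0.779934
679,0.778088
680,0.776244
681,0.774402
682,0.772563
683,0.770726
684,0.768891
685,0.767058
686,0.765228
687,0.763399
688,0.761574
689,0.75975
690,0.757929
691,0.75611
692,0.754294
693,0.75248
694,0.750669
695,0.74886
696,0.747054
697,0.74525
698,0.743449
699,0.74165
700,0.739854
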