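magnetometer:
  LF:
  - MEG0071
  - MEG0081
  - MEG0091
  - MEG0151
  - MEG0161
  - MEG0171
  - MEG0181
  - MEG0191
  - MEG0271
  - MEG0281
  - MEG0291
  - MEG0301
  - MEG0311
  - MEG0321
  - MEG0331
  - MEG0411
  - MEG0421
  - MEG0431
  - MEG0441
  - MEG0451
  - MEG0461
  - MEG0471
  RF:
  - MEG0551
  - MEG0561
  - MEG0571
  - MEG0631
  - MEG0641
  - MEG0651
  - MEG0661
  - MEG0671
  - MEG0751
  - MEG0761
  - MEG0771
  - MEG0781
  - MEG0791
  - MEG0801
  - MEG0811
  - MEG0891
  - MEG0901
  - MEG0911
  - MEG0921
  - MEG0931
  - MEG0941
  - MEG0951
  LT:
  - MEG0341
  - MEG0351
  - MEG0361
  - MEG0481
  - MEG0491
  - MEG0501
  - MEG0511
  RT:
  - MEG0821
  - MEG0831
  - MEG0841
  - MEG0961
  - MEG0971
  - MEG0981
  - MEG0991
  LC:
  - MEG0101
  - MEG0111
  - MEG0121
  - MEG0131
  - MEG0201
  - MEG0211
  - MEG0221
  RC:
  - MEG0581
  - MEG0591
  - MEG0601
  - MEG0611
  - MEG0681
  - MEG0691
  - MEG0701
  LP:
  - MEG0141
  - MEG0231
  - MEG0241
  - MEG0251
  - MEG0261
  - MEG0371
  RP:
  - MEG0621
  - MEG0711
  - MEG0721
  - MEG0731
  - MEG0741
  - MEG0851
  LO:
  - MEG0381
  - MEG0391
  - MEG0401
  - MEG0521
  - MEG0531
  - MEG0541
  RO:
  - MEG0861
  - MEG0871
  - MEG0881
  - MEG1001
  - MEG1011
  - MEG1021
gradiometer:
  LF:
  - MEG0152
  - MEG0153
  - MEG0162
  - MEG0163
  - MEG0172
  - MEG0173
  - MEG0272
  - MEG0273
  - MEG0282
  - MEG0283
  - MEG0292
  - MEG0293
  - MEG0302
  - MEG0303
  - MEG0412
  - MEG0413
  - MEG0422
  - MEG0423
  - MEG0432
  - MEG0433
  - MEG0442
  - MEG0443
  RF:
  - MEG0632
  - MEG0633
  - MEG0642
  - MEG0643
  - MEG0652
  - MEG0653
  - MEG0752
  - MEG0753
  - MEG0762
  - MEG0763
  - MEG0772
  - MEG0773
  - MEG0782
  - MEG0783
  - MEG0892
  - MEG0893
  - MEG0902
  - MEG0903
  - MEG0912
  - MEG0913
  - MEG0922
  - MEG0923
  LT:
  - MEG0312
  - MEG0313
  - MEG0322
  - MEG0323
  - MEG0332
  - MEG0333
  - MEG0342
  - MEG0343
  - MEG0452
  - MEG0453
  - MEG0462
  - MEG0463
  - MEG0472
  - MEG0473
  - MEG0482
  - MEG0483
  - MEG0492
  - MEG0493
  - MEG0502
  - MEG0503
  RT:
  - MEG0792
  - MEG0793
  - MEG0802
  - MEG0803
  - MEG0812
  - MEG0813
  - MEG0822
  - MEG0823
  - MEG0932
  - MEG0933
  - MEG0942
  - MEG0943
  - MEG0952
  - MEG0953
  - MEG0962
  - MEG0963
  - MEG0972
  - MEG0973
  - MEG0982
  - MEG0983
  LC:
  - MEG0072
  - MEG0073
  - MEG0082
  - MEG0083
  - MEG0092
  - MEG0093
  - MEG0102
  - MEG0103
  - MEG0112
  - MEG0113
  - MEG0182
  - MEG0183
  - MEG0192
  - MEG0193
  - MEG0202
  - MEG0203
  - MEG0212
  - MEG0213
  RC:
  - MEG0552
  - MEG0553
  - MEG0562
  - MEG0563
  - MEG0572
  - MEG0573
  - MEG0582
  - MEG0583
  - MEG0592
  - MEG0593
  - MEG0662
  - MEG0663
  - MEG0672
  - MEG0673
  - MEG0682
  - MEG0683
  - MEG0692
  - MEG0693
  LP:
  - MEG0122
  - MEG0123
  - MEG0132
  - MEG0133
  - MEG0142
  - MEG0143
  - MEG0222
  - MEG0223
  - MEG0232
  - MEG0233
  - MEG0242
  - MEG0243
  - MEG0352
  - MEG0353
  - MEG0362
  - MEG0363
  - MEG0372
  - MEG0373
  RP:
  - MEG0602
  - MEG0603
  - MEG0612
  - MEG0613
  - MEG0622
  - MEG0623
  - MEG0702
  - MEG0703
  - MEG0712
  - MEG0713
  - MEG0722
  - MEG0723
  - MEG0832
  - MEG0833
  - MEG0842
  - MEG0843
  - MEG0852
  - MEG0853
  LO:
  - MEG0252
  - MEG0253
  - MEG0262
  - MEG0263
  - MEG0382
  - MEG0383
  - MEG0392
  - MEG0393
  - MEG0402
  - MEG0403
  - MEG0512
  - MEG0513
  - MEG0522
  - MEG0523
  - MEG0532
  - MEG0533
  - MEG0542
  - MEG0543
  RO:
  - MEG0732
  - MEG0733
  - MEG0742
  - MEG0743
  - MEG0862
  - MEG0863
  - MEG0872
  - MEG0873
  - MEG0882
  - MEG0883
  - MEG0992
  - MEG0993
  - MEG1002
  - MEG1003
  - MEG1012
  - MEG1013
  - MEG1022
  - MEG1023
excluded:
- MEG0011
- MEG0012
- MEG0013
- MEG0021
- MEG0022
- MEG0023
- MEG0031
- MEG0032
- MEG0033
- MEG0041
- MEG0042
- MEG0043
- MEG0051
- MEG0052
- MEG0053
- MEG0061
- MEG0062
- MEG0063
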