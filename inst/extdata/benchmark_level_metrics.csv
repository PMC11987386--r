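method,threshold,level,n_selected,acc,precision,recall,f1,specificity,ba,auc
majority_voting,3,1,24,1,1,1,1,1,1,1
majority_voting,3,2,24,0.8812,0.8906,0.9194,0.9048,0.8205,0.8699,0.9421
majority_voting,3,3,23,0.9355,0.9512,0.9512,0.9512,0.9048,0.9280,0.9628
majority_voting,3,4,25,0.9512,1,0.8182,0.9000,1,0.9091,0.9788
majority_voting,3,5,22,0.9667,1,0.9474,0.9730,1,0.9737,0.9904
majority_voting,3,6,24,1,1,1,1,1,1,1
majority_voting,3,7,24,1,1,1,1,1,1,1
majority_voting,2,1,28,1,1,1,1,1,1,1
majority_voting,2,2,27,0.8911,0.9048,0.9194,0.9120,0.8462,0.8828,0.9400
majority_voting,2,3,33,0.9355,0.9512,0.9512,0.9512,0.9048,0.9280,0.9652
majority_voting,2,4,31,0.9268,1,0.7273,0.8421,1,0.8636,0.9667
majority_voting,2,5,31,0.9333,0.9474,0.9474,0.9474,0.9091,0.9282,0.9856
majority_voting,2,6,32,0.8000,0.8750,0.7000,0.7778,0.9000,0.8000,0.9700
majority_voting,2,7,28,1,1,1,1,1,1,1
majority_voting,4,1,20,0.9945,1,0.9901,0.9951,1,1,1
majority_voting,4,2,21,0.8515,0.8730,0.8871,0.8800,0.7949,0.8410,0.9218
majority_voting,4,3,17,0.8548,0.9211,0.9211,0.8861,0.8571,0.8554,0.9384
majority_voting,4,4,18,0.9024,0.8889,0.7273,0.8000,0.9667,0.8470,0.9394
majority_voting,4,5,15,0.9667,1,0.9474,0.9730,1,0.9737,0.9856
majority_voting,4,6,17,0.9500,1,0.9000,0.9474,1,0.9500,0.9900
majority_voting,4,7,21,1,1,1,1,1,1,1
evo,NA,1,22,0.9780,0.9899,0.9703,0.9800,0.9877,0.9790,0.9978
evo,NA,2,27,0.8218,0.8548,0.8548,0.8548,0.7692,0.8120,0.9289
evo,NA,3,21,0.9194,0.9286,0.9512,0.9398,0.8571,0.9042,0.9663
evo,NA,4,15,0.9024,0.8889,0.7273,0.8000,0.9667,0.8470,0.9515
evo,NA,5,22,0.8000,0.8824,0.7895,0.8333,0.8182,0.8038,0.9282
evo,NA,6,17,0.8000,0.7143,1,0.8333,0.6000,0.8000,0.9700
evo,NA,7,19,1,1,1,1,1,1,1
fla,NA,1,17,0.9835,0.9712,1,0.9854,0.9630,0.9815,0.9996
fla,NA,2,23,0.8515,0.8852,0.8710,0.8780,0.8205,0.8457,0.9264
fla,NA,3,20,0.9194,0.9500,0.9268,0.9383,0.9048,0.9158,0.9774
fla,NA,4,19,0.9268,1,0.7273,0.8421,1,0.8636,0.9803
fla,NA,5,16,0.9333,0.9474,0.9474,0.9474,0.9091,0.9282,0.9904
fla,NA,6,27,0.6000,0.7500,0.3000,0.4286,0.9000,0.6000,0.8700
fla,NA,7,24,1,1,1,1,1,1,1
fox,NA,1,23,0.9780,0.9802,0.9802,0.9802,0.9753,0.9778,0.9947
fox,NA,2,21,0.8416,0.8382,0.9194,0.8769,0.7179,0.8187,0.9264
fox,NA,3,27,0.9194,0.9500,0.9268,0.9383,0.9048,0.9158,0.9762
fox,NA,4,18,0.8293,1,0.3636,0.5333,1,0.6818,0.9045
fox,NA,5,21,0.8333,0.8889,0.8421,0.8649,0.8182,0.8301,0.9426
fox,NA,6,22,0.8000,0.8000,0.8000,0.8000,0.8000,0.8000,0.8000
fox,NA,7,24,1,1,1,1,1,1,1
rime,NA,1,22,0.9945,0.9902,1,0.9951,0.9877,0.9938,0.9999
rime,NA,2,27,0.8119,0.8413,0.8548,0.8480,0.7436,0.7992,0.9272
rime,NA,3,17,0.8871,0.9722,0.8537,0.9091,0.9524,0.9030,0.9599
rime,NA,4,19,0.9024,0.8889,0.7273,0.8000,0.9667,0.8470,0.9288
rime,NA,5,25,0.8667,0.8947,0.8947,0.8947,0.8182,0.8565,0.9569
rime,NA,6,17,0.7500,0.8571,0.6000,0.7059,0.9000,0.7500,0.9300
rime,NA,7,21,1,1,1,1,1,1,1
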