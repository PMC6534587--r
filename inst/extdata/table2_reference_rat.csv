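row,comparison,cutoff,auc,p_label,sensitivity,specificity
1,"Control vs LGD, HGD/CIS, Ca",38.7,0.99,<0.001,93,98
2,"Control vs LGD",39.4,0.99,<0.001,99,99
3,"Control vs HGD",38.5,0.98,<0.001,91,97
4,"Control vs Ca",37.8,0.99,<0.001,93,96
5,"LGD vs HGD",48.7,0.81,<0.001,71,80
6,"LGD vs Ca",52.7,0.70,<0.001,70,60
7,"HGD vs Ca",48.5,0.64,<0.001,57,70
8,"Control, LGD vs HGD, Ca",37.4,0.60,<0.001,94,45
9,"Control, LGD, HGD vs Ca",46.3,0.63,<0.001,68,56
10,"LGD vs HGD, Ca",50.9,0.76,<0.001,70,69
11,"LGD, HGD vs Ca",60.8,0.50,<0.023,96,11
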