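row,comparison,cutoff,auc,p_label,sensitivity,specificity
1,"Control vs LGD",40.4,0.71,<0.001,54,100
2,"Control vs HGD",39.4,0.97,<0.001,96,98
3,"Control vs Ca",32.9,0.58,0.4195,38,100
4,"LGD vs HGD",39.4,0.74,<0.001,98,45
5,"LGD vs Ca",36.8,0.68,0.0074,56,80
6,"HGD vs Ca",38.5,0.80,<0.001,68,96
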