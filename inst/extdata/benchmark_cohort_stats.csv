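metric,comparison,mean,sd,min,max,cv
AD,auto,17.54,16.45,0.0009,113.75,0.9379
AD,manual,19.19,17.69,0.0011,119.54,0.9218
CC,auto,98.10,1.60,92.92,99.76,0.0163
CC,manual,98.59,1.12,94.48,99.91,0.0114
DC,auto,89.48,5.03,76.88,96.47,0.0562
DC,manual,89.12,5.68,75.35,97.34,0.0637
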