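system,patient,sensitivity_pct,advance1_min,advance2_min,advance3_min,fpr_per_h
no_update,4,100,79.1,58.7,62.6,0.03
no_update,5,66.7,0,24.3,43.8,0.00
no_update,9,100,67.8,59.2,81.3,0.00
no_update,10,100,18.4,27.3,76.0,0.00
no_update,16,66.7,73.3,10.9,0,0.03
no_update,17,33.3,108.3,0,0,0.38
no_update,18,100,38.3,63.3,93.8,0.11
no_update,20,66.7,0,26.9,36.9,0.17
no_update,21,100,108.2,102.5,76.0,0.21
dynamic,4,100,79.0,56.2,63.5,0.00
dynamic,5,66.7,17.5,0,22.0,0.03
dynamic,9,100,67.8,59.2,81.3,0.00
dynamic,10,100,20.3,27.1,76.4,0.07
dynamic,16,66.7,45.0,23.8,0,0.00
dynamic,17,66.7,52.8,0,33.3,0.14
dynamic,18,100,38.3,68.5,93.7,0.00
dynamic,20,66.7,0,30.9,37.5,0.12
dynamic,21,100,107.2,103.0,61.5,0.00
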