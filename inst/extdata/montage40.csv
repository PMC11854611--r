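label,x,y,z,hemisphere
AF3,-0.3894,0.8878,0.2453,left
AF4,0.4044,0.8801,0.2486,right
F7,-0.8476,0.5124,-0.1378,left
F8,0.8461,0.5146,-0.139,right
FT9,-0.8483,0.147,-0.5088,left
FT10,0.8481,0.1448,-0.5096,right
FC3,-0.7081,0.2673,0.6535,left
FC4,0.7175,0.2732,0.6407,right
FC5,-0.929,0.2243,0.2943,left
FC6,0.9296,0.233,0.2856,right
C1,-0.3717,-0.1026,0.9227,left
C2,0.39,-0.0996,0.9154,right
C5,-0.928,-0.159,0.3371,left
C6,0.9342,-0.143,0.3269,right
CP1,-0.3264,-0.4347,0.8393,left
CP2,0.3516,-0.4313,0.8309,right
CP3,-0.6186,-0.4575,0.6387,left
CP4,0.6376,-0.4464,0.6278,right
TP7,-0.8766,-0.4756,-0.0729,left
TP8,0.8803,-0.4687,-0.0734,right
P7,-0.7019,-0.7118,-0.0241,left
P8,0.7068,-0.707,-0.0246,right
PO3,-0.3216,-0.8885,0.3274,left
PO4,0.3245,-0.8897,0.3211,right
PO7,-0.49,-0.8714,0.0249,left
PO8,0.4952,-0.8684,0.0243,right
Fz,0.0035,0.6608,0.7506,midline
F3,-0.5952,0.6292,0.4998,left
F4,0.6066,0.6355,0.4776,right
C3,-0.7069,-0.1258,0.6961,left
C4,0.721,-0.1171,0.683,right
Cz,0.004,-0.0911,0.9958,midline
T7,-0.9766,-0.1859,-0.1084,left
T8,0.9789,-0.1728,-0.1092,right
P3,-0.481,-0.7149,0.5076,left
P4,0.4985,-0.7035,0.5065,right
Pz,0.0028,-0.7006,0.7136,midline
O1,-0.2523,-0.9647,0.0758,left
O2,0.2564,-0.9636,0.0756,right
Oz,0.0009,-0.992,0.1265,midline
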