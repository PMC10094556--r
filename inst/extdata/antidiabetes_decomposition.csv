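row,ECt,CGt,ECGt,GCe,EGCe,GCGe,EGCGe,Ce,ECe,ECGe
ECt,0.3837,-0.3418,-0.3545,-0.34,0.1923,0.2975,-0.0765,0.3536,0.3542,0.3378
CGt,0.5586,-0.627,-0.6118,-0.4284,0.5211,0.5847,-0.2872,0.5662,0.5542,0.614
ECGt,1.05,-1.109,-1.1364,-0.914,0.8405,0.9913,-0.5774,0.9805,0.9661,1.1299
GCe,0.0257,-0.0198,-0.0233,-0.029,0.0069,0.014,-0.0075,0.0197,0.0199,0.0218
EGCe,-0.0759,0.1258,0.112,0.0361,-0.1514,-0.1288,0.085,-0.092,-0.0923,-0.1203
GCGe,0.1012,-0.1217,-0.1139,-0.063,0.111,0.1305,-0.0471,0.1069,0.1134,0.1149
EGCGe,-0.0014,0.0032,0.0035,0.0018,-0.0039,-0.0025,0.007,-0.0013,-2e-04,-0.004
Ce,0.5587,-0.5475,-0.5231,-0.4118,0.3685,0.4966,-0.1125,0.6063,0.5477,0.508
ECe,-0.5354,0.5126,0.493,0.3982,-0.3536,-0.5036,0.0146,-0.5238,-0.5799,-0.4713
ECGe,-1.1012,1.2249,1.2436,0.9407,-0.9937,-1.1014,0.7188,-1.0481,-1.0167,-1.2508
Sum of indirect effects,0.5803,-0.2734,0.2255,-0.7804,0.6891,0.6477,-0.2898,0.3617,1.4463,2.1308
Total effect (rjy),0.964,-0.9004,-0.9109,-0.8094,0.5377,0.7782,-0.2828,0.968,0.8664,0.88
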