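row,ECt,CGt,ECGt,GCe,EGCe,GCGe,EGCGe,Ce,ECe,ECGe
ECt,0.3521,-0.3137,-0.3253,-0.3121,0.1765,0.273,-0.0702,0.3245,0.3251,0.31
CGt,-0.4532,0.5087,0.4964,0.3476,-0.4228,-0.4744,0.233,-0.4594,-0.4497,-0.4982
ECGt,0.0254,-0.0268,-0.0274,-0.0221,0.0203,0.0239,-0.0139,0.0237,0.0233,0.0273
GCe,-0.1795,0.1384,0.1629,0.2026,-0.0483,-0.0978,0.0522,-0.1376,-0.1391,-0.1524
EGCe,-0.0821,0.136,0.1211,0.039,-0.1637,-0.1392,0.0919,-0.0995,-0.0998,-0.13
GCGe,0.1237,-0.1488,-0.1392,-0.077,0.1358,0.1596,-0.0576,0.1307,0.1386,0.1405
EGCGe,6e-04,-0.0014,-0.0016,-8e-04,0.0017,0.0011,-0.0031,6e-04,1e-04,0.0018
Ce,0.3142,-0.3079,-0.2941,-0.2316,0.2072,0.2792,-0.0633,0.3409,0.3079,0.2857
ECe,-0.1416,0.1356,0.1304,0.1053,-0.0936,-0.1332,0.0039,-0.1386,-0.1534,-0.1247
ECGe,0.9787,-1.0886,-1.1053,-0.8361,0.8832,0.9789,-0.6388,0.9315,0.9036,1.1117
Sum of indirect effects,0.5861,-1.4772,-0.9548,-0.9876,0.8601,0.7115,-0.4629,0.5759,1.01,-0.1401
Total effect (rjy),0.9382,-0.9685,-0.9822,-0.785,0.6964,0.8711,-0.466,0.9168,0.8566,0.9716
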