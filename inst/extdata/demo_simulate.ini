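# demo synthetic dataset: 6 correlated units, strong signal
m = 6
rho = 0.4
b = 1.0, -0.8, 0.5, 0.3, -0.2, 0.1
noise_sd = 0.5
n = 60
seed = 42
units = ECt, CGt, ECGt, Ce, ECe, ECGe
activity = antioxidant
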