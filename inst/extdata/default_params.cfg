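# Calibrated baseline parameters of the 12-state KCNQ1 gating model.
# Derived once by the calibration procedure described in the methods
# vignette (slow sigmoidal activation at +20 mV, mono-exponential
# tail at -120 mV, F(V) hyperpolarized relative to G(V)).
alpha0 = 7.9
z_alpha = 1.55
beta0 = 1
z_beta = 0.55
theta0 = 6
z_theta = 0.3
eta0 = 0.0314
z_eta = 2
ko0 = 0.206
kc0 = 36
L = 3
D = 6
x_split = 0.1
Gmax = 1
E_K = -105
w_I = 0.8
w_A = 1
VT = 25.4
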