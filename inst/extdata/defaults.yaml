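# Default parameterization of the size-structured DEB consumer-resource
# model. Units: resource densities mg/L, body masses g, rates per day.
Rmax: 30.0
delta: 0.01
Q: 1.0
P: 1.0
M: 0.1
T: 0.01
mu_c: 0.0015
mu_j: 0.0
mu_a: 0.0
sigma: 0.5
H: 3.0
s_b: 0.1
s_j: 1.0
s_m: 10.0
s_r: 1.0
s_rI: 1.0
s_rT: 1.0
chi: 1.0
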