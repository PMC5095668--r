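# 256-subunit-pore model (Model II) rate constants and pore size.
# Identical to the tetramer model except for the pore size and the CytC
# translocation rate. Units: concentrations nM, times seconds.
pore_size: 256
sigma_M: 5.0e-6
delta_M: 1.3e-4
alpha_M: 0.05
beta_M: 0.5
alpha_12: 0.05
beta_12: 500.0
alpha_24: 0.05
beta_24: 0.05
alpha_other: 1.0
beta_other: 1.0
gamma_m: 0.5
gamma_c: 0.5
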