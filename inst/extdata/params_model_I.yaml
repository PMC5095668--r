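# Tetramer-pore model (Model I) rate constants and pore size.
# Units: concentrations nM, times seconds.
pore_size: 4
sigma_M: 5.0e-6       # Mcl-1 synthesis rate in mitosis (nM/s)
delta_M: 1.3e-4       # Mcl-1 degradation rate in mitosis (1/s)
alpha_M: 0.05         # Bak/Mcl-1 association rate (1/nM/s)
beta_M: 0.5           # Bak/Mcl-1 dissociation rate (1/s)
alpha_12: 0.05        # Bak dimerization rate (1/nM/s)
beta_12: 500.0        # Bak dimer dissociation rate (1/s)
alpha_24: 0.05        # Bak tetramer association rate (1/nM/s)
beta_24: 0.05         # Bak tetramer dissociation rate (1/s)
alpha_other: 1.0      # association rate of all other oligomers (1/nM/s)
beta_other: 1.0       # dissociation rate of all other oligomers (1/s)
gamma_m: 5000.0       # CytC cytoplasmic translocation rate (1/nM/s)
gamma_c: 0.5          # CytC mitochondrial return rate (1/s)
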