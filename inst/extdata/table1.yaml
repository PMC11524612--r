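# Constant parameters of the single-compartment model (published values).
# Entries not listed here (E_hco3, r_hco3, nernst_coef, tau_ion, closure
# constants, gaba_sign) take the package defaults.
C: 1.0        # membrane capacitance, uF/cm^2
gNa: 30.0     # maximal sodium conductance, mS/cm^2
gK: 20.0      # maximal potassium conductance, mS/cm^2
gNaL: 0.04    # sodium leak, mS/cm^2
gKL: 0.1      # potassium leak, mS/cm^2
gClL: 0.1     # chloride leak, mS/cm^2
gamma: 0.03   # current-to-flux conversion, mM cm^2 s^-1 uA^-1
rho: 0.8      # maximal Na/K pump rate, mM/s
U_nkcc1: 0.1  # NKCC1 strength, mM/s
U_kcc2: 0.3   # KCC2 strength, mM/s
eps_k: 0.25   # maximal potassium diffusion rate, 1/s
K_bath: 3.0   # normal bath potassium, mM
beta: 7.0     # intra/extracellular volume ratio
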