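# Synthetic "plausible-demo" parameter set: physiologically ordered values
# satisfying every model invariant, NOT transcribed from any publication.
# Used by examples and tests that must not depend on a literature fixture.
# Matches the defaults of lileyParameters().  Units: mV, ms, 1/ms.

[membrane]
h_e_rest = -68.0
h_i_rest = -68.0
tau_e = 10.0
tau_i = 40.0

[synaptic]
h_e_eq = 40.0
h_i_eq = -85.0
Gamma_ee = 0.3
Gamma_ei = 0.6
Gamma_ie = 0.3
Gamma_ii = 0.6
gamma_ee = 0.25
gamma_ei = 0.07
gamma_ie = 0.25
gamma_ii = 0.07

[sigmoid]
S_e_max = 0.25
S_i_max = 0.25
mu_e = -46.0
mu_i = -46.0
sigma_e = 5.0
sigma_i = 5.0

[connectivity]
N_ee = 3000.0
N_ei = 500.0
N_ie = 3000.0
N_ii = 500.0

[inputs]
p_ee = 2.0
p_ei = 1.0
p_ie = 0.0
p_ii = 0.0
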