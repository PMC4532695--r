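# Macrocolumnar Liley model parameter set transcribed from the literature:
# Dafilis MP, Frascoli F, Cadusch PJ, Liley DTJ,
# "Four-dimensional chaos and intermittency in a mesoscopic model of the
# electroencephalogram", Chaos 23:023111 (2013), doi:10.1063/1.4804176,
# and the earlier chaotic operating regime of
# Dafilis MP, Liley DTJ, Cadusch PJ, Chaos 11:474 (2001).
# The [inputs] table holds the published operating point at which the model
# is reported to exhibit four-dimensional chaos; sweeps override p_ee, p_ei.
# CAVEAT: transcribed from the secondary literature, not from the original
# machine-readable tables; this transcription does NOT reproduce the
# published exponents (9.6, 0, -6.4, -11.5) s^-1 at the operating point
# (see the methods vignette).  Correct this file if you have the original
# tables, and rerun tests/testthat/test-acceptance.R.
# Subscripts are target-source (jk = at population j, from synapse type k):
# p_ei is external inhibitory drive onto the excitatory population.
# Units: potentials mV, times ms, rates 1/ms.

[membrane]
h_e_rest = -70.0
h_i_rest = -70.0
tau_e = 9.0
tau_i = 39.0

[synaptic]
h_e_eq = 45.0
h_i_eq = -90.0
Gamma_ee = 0.18
Gamma_ei = 0.37
Gamma_ie = 0.18
Gamma_ii = 0.37
gamma_ee = 0.3
gamma_ei = 0.065
gamma_ie = 0.3
gamma_ii = 0.065

[sigmoid]
S_e_max = 0.5
S_i_max = 0.5
mu_e = -50.0
mu_i = -50.0
sigma_e = 5.0
sigma_i = 5.0

[connectivity]
N_ee = 3034.0
N_ei = 536.0
N_ie = 3034.0
N_ii = 536.0

[inputs]
p_ee = 24.2453
p_ei = 2.299
p_ie = 0.0
p_ii = 0.0
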