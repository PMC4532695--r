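# shared fixtures: the synthetic demo parameter set and short spectrum
# options used to keep unit tests fast
demoParams <- function(...) setLileyParameters(lileyParameters(), ...)

shortOpts <- list(tTransient = 2000, tRun = 5000)

# decoupled variant: no synaptic feedback (N = p = 0), so the resting
# state is the exact global equilibrium and each block is linear
decoupledParams <- function(...) {
  setLileyParameters(lileyParameters(),
                     N_ee = 0, N_ei = 0, N_ie = 0, N_ii = 0,
                     p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0, ...)
}
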