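# Reference parameterizations used across tests.
# "alpha_base": gains/decay times whose stable focus rings in the alpha band
# (N1 = 1.1, N2(1) = 0.2236, tau1 = 2 ms, tau2(1) = 20 ms).
# "alpha_base_lowN2": same but N2(1) = 0.25128 (tau2/tau1 = 10 variant).
alpha_base <- function(noise_D = 1, p = 1)
  model_params(1.1, 0.2236, 0.002, 0.02, noise_D = noise_D, p = p)

alpha_base_lowN2 <- function(noise_D = 1, p = 1)
  model_params(1.1, 0.25128, 0.002, 0.02, noise_D = noise_D, p = p)

# Figure-quality stable-focus fixtures shared by several property tests.
stable_fixtures <- function(n, seed = 101)
  generate_fixtures(fixture_spec(n, seed = seed))
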