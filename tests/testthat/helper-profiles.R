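# Shared fixtures: profiles built in code, no stored data.

# The moderate-nitrogen reference leaf used across tests.
mn_profile <- function(anet_sd = 0, fluor_sd = 0, trait_sd = NULL) {
  leaf_profile(
    treatment = "MN", A_max = 3.437, alpha = 0.05, C0 = 1.151,
    Vcmax = 20.771, Jmax = 74.518, gm_true = 0.26, Gamma_star = 99.259,
    SLN = 1.245, chl = 31.618,
    pigments = c(N = 0.865, V = 0.267, A = 0.043, Z = 0.032, L = 3.018,
                 beta_car = 1.59),
    Sc = 12.01, Clip = 0.46, rubisco_content = 10.057,
    rubisco_activity = 40.51,
    noise_sd = list(anet = anet_sd, gs = 0, fluor = fluor_sd),
    trait_sd = trait_sd)
}

# Random but physiologically plausible profile for property-style tests.
random_profile <- function(noise = 0) {
  leaf_profile(
    treatment = "X",
    A_max = stats::runif(1, 1.5, 6), alpha = stats::runif(1, 0.02, 0.08),
    C0 = stats::runif(1, 1.02, 1.5),
    Vcmax = stats::runif(1, 10, 40), Jmax = stats::runif(1, 50, 120),
    gm_true = stats::runif(1, 0.05, 0.4),
    Gamma_star = stats::runif(1, 40, 130),
    SLN = stats::runif(1, 0.5, 2.5), chl = stats::runif(1, 10, 60),
    Sc = stats::runif(1, 6, 15), Clip = stats::runif(1, 0.05, 0.5),
    rubisco_content = stats::runif(1, 5, 70),
    rubisco_activity = stats::runif(1, 1, 50),
    noise_sd = list(anet = noise, gs = 0, fluor = 0))
}

# Random fluorescence step honouring Fo <= Fo' <= Fs <= Fm' <= Fm.
random_fluor_step <- function() {
  y <- sort(stats::runif(5, 10, 5000))
  list(Fo = y[1], Fop = y[2], Fs = y[3], Fmp = y[4], Fm = y[5])
}
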