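# Shared deterministic fixtures, built in code.

test_bank <- function(seed = 99) {
  withr::with_seed(seed, synthetic_duration_bank())
}

# minimal valid bank with constant durations (normal 90 min, arrests 200)
constant_bank <- function(nor = 90, arrest = 200) {
  duration_bank(nor_A = nor, nor_B = nor, nta = arrest, sen = arrest)
}

# degenerate initial distribution: every telomere has length `l`
point_dist <- function(l) {
  initial_distribution(l_inf = l, l_mode = l, l_sup = l, l_0 = 0, l_1 = 0)
}

# parameters with every stochastic arrest/death channel switched off
# (telomeres must stay above 0 over the simulated horizon for the hard
# thresholds at l = 0 to stay inactive)
immortal_params <- function(...) {
  law_params(a_nta = 0, b_nta = 0, a_sen_A = 0, b_sen_A = 0,
             a_sen_B = 0, b_sen_B = 0, l_min_A = 0, l_min_B = 0,
             p_accident = 0, p_death = 0, ...)
}
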