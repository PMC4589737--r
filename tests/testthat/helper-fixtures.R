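# shared fixtures, all generated in code

grid9 <- 10^seq(-2, 2, by = 0.5)  # 9 concentrations over 4 decades

mono_model <- function(ec50 = 1, h = 1.5, e_inf = 0.05) {
  multiphasic_model(hill_phase(ec50, h, e_inf))
}

biphasic_2i_model <- function() {
  multiphasic_model(list(hill_phase(0.01, 2, 0.5), hill_phase(10, 2, 0.05)))
}

hormetic_model <- function() {
  multiphasic_model(list(hill_phase(0.01, 2, 1.4), hill_phase(1, 2, 0.05)))
}

# a random valid model with k phases of the given roles
random_model <- function(roles, lec_range = c(-2, 2)) {
  k <- length(roles)
  lec <- sort(stats::runif(k, lec_range[1], lec_range[2]))
  phases <- lapply(seq_len(k), function(i) {
    e <- if (roles[i] == "stimulatory") stats::runif(1, 1.1, 1.6)
         else stats::runif(1, 0, 0.6)
    hill_phase(10^lec[i], stats::runif(1, 0.5, 3), e)
  })
  multiphasic_model(phases)
}

random_dataset <- function(model, n_rep = 3, sigma = 0.05, seed = 1) {
  simulate_curve(model, grid9, n_rep, sigma, seed = seed)
}
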