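# shared fixtures: the package's default parameterization plus small/fast
# variants used across test files
default_model <- function(...) model_params(...)

short_passage <- function(n_cycles = 30, burn_in_cycles = 10, ...) {
  passage_params(n_cycles = n_cycles, burn_in_cycles = burn_in_cycles, ...)
}

tiny_meta <- function(M = 6, n_cycles = 5, seed = 1, ...) {
  metapop_params(M = M, n_cycles = n_cycles, seed = seed, ...)
}

# closed-form logistic growth, the independent oracle for single-strain runs
logistic_solution <- function(N0, r, K, t) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}
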