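# Shared fixture builders for the suite. Everything is generated in code at
# test time; no stored data.

# Small two-class table with a controllable class-mean gap.
make_table <- function(n_per_class = 50, d = 8, mean_shift = 2, seed = 1) {
  generate_two_class_features(synth_spec(
    n_class0 = n_per_class, n_class1 = n_per_class, dim = d,
    mean_shift = mean_shift, sigma = 1, shifted_fraction = 0.5, seed = seed
  ))
}

# Head configuration small enough for grid searches in tests.
tiny_head <- function(seed = 7, epochs = 6) {
  head_config(epochs = epochs, batch_size = 64, dense_units = 32,
              early_stop_patience = 3, seed = seed)
}

# Naive two-pass population variance, the oracle for the window fitness.
naive_window_variance <- function(positions, index) {
  n <- length(positions)
  start <- min(max(index - 2L, 1L), n - 4L)
  w <- positions[start:(start + 4L)]
  mu <- sum(w) / 5
  sum((w - mu)^2) / 5
}

# Default parameter record per algorithm (exported constructors only).
default_params_for_test <- function(alg) {
  switch(alg, mgto = , gto = mgto_params(), pso = pso_params(),
         eho = eho_params())
}

# Wide bounds used when pinning update-equation draws.
wide_bounds <- scalar_bounds(-100, 100)

# Coefficient list for pinned-draw update tests; fields mirror
# swarm_coefficients() output.
pin_coeffs <- function(C = 0, L = 0, Z = 0, rad = 0, Q = 0, A = 0, g = 1) {
  list(C = C, L = L, Z = Z, rad = rad, Q = Q, A = A, g = g)
}
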