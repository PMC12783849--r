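# Baseline parameterizations used across the suite: the fixation experiments
# use r_w = 1, d_w = 0.1 (only the death-to-birth ratio matters for fixation
# probabilities); the mutation time-series experiments use r_w = 5, d_w = 0.5.

base_rates <- function(tau = 1, s = 0) kinetic_rates(1, 0.1, tau, s)
mut_rates <- function(tau = 1, s = 0) kinetic_rates(5, 0.5, tau, s)

base_config <- function(K = 20, D = 1, epsilon = 0, ...) {
  deme_config(K = K, D = D, epsilon = epsilon, ...)
}

# brute-force single-mutant fixation probability of the death-birth Moran
# chain: enumerate the (N+1)-state embedded chain on mutant counts and solve
# the absorption system directly
moran_db_brute_force <- function(N, tau) {
  p_up <- p_dn <- numeric(N + 1)
  for (j in seq_len(N - 1)) {
    # death weights: mutants j*tau, wild types (N - j); replacement weights
    # among the remaining N - 1 individuals
    p_up[j + 1] <- (N - j) / ((N - j) + j * tau) *
      (j * tau) / (j * tau + (N - j - 1))
    p_dn[j + 1] <- (j * tau) / ((N - j) + j * tau) *
      (N - j) / ((N - j) + (j - 1) * tau)
  }
  # absorption probability at j = N via linear solve over transient 1..N-1
  A <- matrix(0, N - 1, N - 1)
  b <- numeric(N - 1)
  for (j in seq_len(N - 1)) {
    tot <- p_up[j + 1] + p_dn[j + 1]
    A[j, j] <- tot
    if (j > 1) A[j, j - 1] <- -p_dn[j + 1]
    if (j < N - 1) A[j, j + 1] <- -p_up[j + 1]
    if (j == N - 1) b[j] <- p_up[j + 1]
  }
  solve(A, b)[1]
}
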