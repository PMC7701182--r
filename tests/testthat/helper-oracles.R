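# Independent oracles used by the evolution tests. These deliberately avoid
# the code paths they check: fixation is obtained from a numerical linear
# solve of the absorbing birth-death chain, and the small-mutation-limit
# stationary distribution from a direct simulation of the rare-mutation
# imitation process.

# Payoff profiles pi_A(k), pi_B(k) for k = 1..Z-1 copies of A.
pair_payoff_profiles <- function(A, B, pop) {
  t(vapply(seq_len(pop$Z - 1), function(k) pairwise_payoff(A, B, k, pop),
           numeric(2)))
}

# Fixation probability of one A-mutant among B-residents, solved from the
# absorbing tridiagonal birth-death chain (states 0..Z copies of A).
oracle_fixation_bd <- function(A, B, pop) {
  Z <- pop$Z; beta <- pop$beta
  prof <- pair_payoff_profiles(A, B, pop)
  dpi <- prof[, 1] - prof[, 2]
  fermi <- function(x) 1 / (1 + exp(-x))
  i <- seq_len(Z - 1)
  Tp <- (Z - i) / Z * i / (Z - 1) * fermi(beta * dpi)
  Tm <- i / Z * (Z - i) / (Z - 1) * fermi(-beta * dpi)
  # h_i = P(absorb at Z | start i); h_0 = 0, h_Z = 1
  # (1 - stay) h_i - Tp h_{i+1} - Tm h_{i-1} = 0
  M <- matrix(0, Z - 1, Z - 1)
  b <- numeric(Z - 1)
  for (ii in i) {
    M[ii, ii] <- Tp[ii] + Tm[ii]
    if (ii > 1) M[ii, ii - 1] <- -Tm[ii]
    if (ii < Z - 1) M[ii, ii + 1] <- -Tp[ii]
    if (ii == Z - 1) b[ii] <- Tp[ii]
  }
  solve(M, b)[1]
}

# One simulated invasion: does a single A-mutant fix among B-residents?
# Simulated as the self-loop-free jump chain of the pairwise-comparison
# process: from state i the count moves up with probability
# sigmoid(beta * (pi_A(i) - pi_B(i))).
simulate_invasion <- function(dpi, Z, beta) {
  i <- 1L
  while (i > 0L && i < Z) {
    p_up <- 1 / (1 + exp(-beta * dpi[i]))
    i <- if (stats::runif(1) < p_up) i + 1L else i - 1L
  }
  i == Z
}

# Direct Monte-Carlo simulation of the rare-mutation imitation process:
# from each monomorphic state, a uniformly chosen mutant strategy attempts
# an invasion simulated step by step; the sequence of monomorphic states is
# the embedded chain. Returns the occupancy estimate and batch-based SEs.
oracle_sml_mc <- function(pop, n_transitions = 4000, n_batches = 10) {
  strat <- names(pop$profiles)
  n <- length(strat)
  dpi_tab <- list()
  for (A in strat) for (B in strat) if (A != B) {
    prof <- pair_payoff_profiles(A, B, pop)
    dpi_tab[[paste(A, B)]] <- prof[, 1] - prof[, 2]
  }
  state <- strat[1]
  visits <- matrix(0, nrow = n_batches, ncol = n,
                   dimnames = list(NULL, strat))
  per_batch <- ceiling(n_transitions / n_batches)
  for (b in seq_len(n_batches)) {
    for (s in seq_len(per_batch)) {
      mut <- sample(setdiff(strat, state), 1)
      if (simulate_invasion(dpi_tab[[paste(mut, state)]], pop$Z, pop$beta))
        state <- mut
      visits[b, state] <- visits[b, state] + 1
    }
  }
  freq <- visits / per_batch
  list(stationary = colMeans(freq),
       se = apply(freq, 2, stats::sd) / sqrt(n_batches))
}

# Brute-force expected payoff of a focal A against B by explicit
# enumeration of co-player compositions with hypergeometric weights,
# using raw choose() arithmetic (no dhyper) and a fresh game replay.
oracle_focal_payoff <- function(A, B, k, pop) {
  Z <- pop$Z; N <- pop$game$N
  tot <- 0
  for (j in 0:(N - 1)) {
    wt <- choose(k - 1, j) * choose(Z - k, N - 1 - j) / choose(Z - 1, N - 1)
    if (wt == 0) next
    profs <- c(rep(list(pop$profiles[[A]]), j + 1),
               rep(list(pop$profiles[[B]]), N - 1 - j))
    out <- expected_outcome(profs, pop$game)
    tot <- tot + wt * out$expected_payoffs[1]
  }
  tot
}
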