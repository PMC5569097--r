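# Independent brute-force oracles: exact Markov-chain enumeration of the
# single-cell dynamics on a 1 x S2 strip, built in plain R from the rule
# definitions (not from the simulation engine).

# direction probabilities for the biased walk
oracle_dir_probs <- function(kappa) {
  w <- c(exp(-kappa), exp(kappa), 1, 1)  # left, right, up, down
  w / sum(w)
}

# Position-only transition matrix for one elementary update of a single
# non-switching cell on a 1 x S2 lattice with homogeneous resistance mu.
# With S1 = 1 the periodic up/down moves land on the cell's own site and
# are aborted; left/right moves abort at the reflecting boundaries.
oracle_position_chain <- function(S2, kappa, mu, c_X) {
  lam <- c_X / (1 + exp(15 * (mu - 0.5)))
  p <- oracle_dir_probs(kappa)
  T <- matrix(0, S2, S2)
  for (j in seq_len(S2)) {
    if (j > 1) T[j, j - 1] <- lam * p[1]
    if (j < S2) T[j, j + 1] <- lam * p[2]
    T[j, j] <- 1 - sum(T[j, ])
  }
  T
}

# Joint (position x phenotype) transition matrix for a single switching
# cell, delta = 0 so the resistance field stays fixed at mu. State index:
# (j, A) -> j, (j, M) -> S2 + j. Rule order within an update: switch first,
# then move with the post-switch phenotype's rate.
oracle_joint_chain <- function(S2, kappa, mu, c_A, c_M, alpha, beta) {
  sA <- alpha * mu          # P(A -> M)
  sM <- beta * (1 - mu)     # P(M -> A)
  TA <- oracle_position_chain(S2, kappa, mu, c_A)
  TM <- oracle_position_chain(S2, kappa, mu, c_M)
  T <- matrix(0, 2 * S2, 2 * S2)
  T[seq_len(S2), seq_len(S2)] <- (1 - sA) * TA
  T[seq_len(S2), S2 + seq_len(S2)] <- sA * TM
  T[S2 + seq_len(S2), seq_len(S2)] <- sM * TA
  T[S2 + seq_len(S2), S2 + seq_len(S2)] <- (1 - sM) * TM
  T
}

# Empirical distribution over (position, phenotype) after n_updates of the
# engine, replicated n_rep times on a 1 x S2 strip; one shared RNG stream.
empirical_joint <- function(S2, kappa, mu, c_A, c_M, alpha, beta,
                            switching, n_updates, n_rep, seed = 1) {
  set.seed(seed)
  counts <- numeric(2 * S2)
  occ0 <- matrix(0L, 1, S2); occ0[1, 1] <- 1L
  ecm0 <- matrix(mu, 1, S2)
  for (k in seq_len(n_rep)) {
    out <- switchmig:::cpp_run_updates(occ0, 1L, 1L, 1L, ecm0, alpha, beta,
                                       c_A, c_M, 0, kappa, switching,
                                       n_updates, 0L)
    idx <- if (out$phen == 1L) out$r2 else S2 + out$r2
    counts[idx] <- counts[idx] + 1
  }
  counts / n_rep
}

# 3-sigma binomial check of empirical vs exact state probabilities
expect_matches_chain <- function(emp, exact_probs, n_rep) {
  tol <- 3 * sqrt(exact_probs * (1 - exact_probs) / n_rep) + 1e-12
  expect_true(all(abs(emp - exact_probs) <= tol),
              info = paste0("max dev ", signif(max(abs(emp - exact_probs)), 3)))
}
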