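# Individual-level Monte Carlo oracle for the cohort engine: walkers are
# propagated one by one through the same per-cycle transition matrices, so
# the empirical occupancy must agree with the deterministic trace within
# binomial sampling error.
microsim_occupancy <- function(arm, params, n_walkers, seed,
                               hr_mode = "rate") {
  set.seed(seed)
  init <- decision_tree_stage(arm, params)$initial
  counts <- drop(stats::rmultinom(1, n_walkers, init))
  n <- params$economics$horizon_cycles
  occ <- matrix(0, n + 1, 7)
  occ[1, ] <- counts / n_walkers
  for (k in seq_len(n)) {
    M <- build_transition_matrix(k, params, hr_mode)
    new_counts <- numeric(7)
    for (s in 1:7) {
      if (counts[s] > 0) {
        new_counts <- new_counts + drop(stats::rmultinom(1, counts[s], M[s, ]))
      }
    }
    counts <- new_counts
    occ[k + 1, ] <- counts / n_walkers
  }
  occ
}
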