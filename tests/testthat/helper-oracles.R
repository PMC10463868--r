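# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: enumeration and direct linear algebra, sharing no
# code path with the implementation they check.

# Brute-force dominance statuses: pairwise weak dominance, then the
# convex-blend test (a survivor beaten by a mixture of two other
# survivors is extendedly dominated, i.e. sits above the lower convex
# hull of the cost-QALY cloud).
oracle_rank_statuses <- function(df) {
  n <- nrow(df)
  status <- rep("non-dominated", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i])) {
        status[i] <- "dominated"
      }
    }
  }
  surv <- which(status != "dominated")
  for (i in surv) {
    for (j in surv) {
      for (k in surv) {
        if (j >= k || i == j || i == k) next
        qj <- df$qaly[j]; qk <- df$qaly[k]
        if (qj == qk) next
        lam <- (df$qaly[i] - qj) / (qk - qj)
        if (lam >= 0 && lam <= 1) {
          blend_cost <- (1 - lam) * df$cost[j] + lam * df$cost[k]
          if (blend_cost < df$cost[i] - 1e-12) status[i] <- "extendedly-dominated"
        }
      }
    }
  }
  status
}

# Trace by explicit matrix powers (independent of the engine's loop).
oracle_trace <- function(init, m, n_cycles) {
  out <- matrix(0, n_cycles + 1, length(init))
  pow <- diag(length(init))
  for (t in 0:n_cycles) {
    out[t + 1, ] <- init %*% pow
    pow <- pow %*% m
  }
  colnames(out) <- colnames(m)
  out
}

# A random row-stochastic matrix with an absorbing terminal state and a
# strictly positive death probability from every alive state.
random_absorbing_matrix <- function(states, min_death = 0.01) {
  n <- length(states)
  m <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n - 1)) {
    w <- stats::rgamma(n, shape = 1)
    w <- w / sum(w)
    # guarantee some death mass
    w[n] <- w[n] + min_death
    m[i, ] <- w / sum(w)
  }
  m[n, n] <- 1
  m
}
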