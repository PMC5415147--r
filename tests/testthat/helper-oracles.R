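# Independent oracles used across the suite.  Everything here is coded
# directly from first principles (array indexing, exhaustive enumeration)
# and deliberately shares no code with the package internals it checks.

# random finite game as a list of payoff arrays (one per player)
rand_payoff_arrays <- function(n_players, n_strategies) {
  if (length(n_strategies) == 1L) {
    n_strategies <- rep(n_strategies, n_players)
  }
  lapply(seq_len(n_players), function(i) {
    array(stats::runif(prod(n_strategies), -1, 1), dim = n_strategies)
  })
}

# u_i(s) straight from the arrays
oracle_payoff <- function(payoffs, i, s) {
  do.call(`[`, c(list(payoffs[[i]]), as.list(s)))
}

# full Nash ascendancy count, Eq-(1) style, written independently:
# iterate every player, substitute q_i into s, compare
oracle_k <- function(payoffs, s, q, tie_leq = TRUE) {
  count <- 0L
  for (i in seq_along(s)) {
    if (s[i] == q[i]) next
    dev <- s
    dev[i] <- q[i]
    u_now <- oracle_payoff(payoffs, i, s)
    u_dev <- oracle_payoff(payoffs, i, dev)
    hit <- if (tie_leq) u_now <= u_dev else u_now < u_dev
    if (hit) count <- count + 1L
  }
  count
}

# restricted count over an explicit subset
oracle_kp <- function(payoffs, s, q, subset, tie_leq = TRUE) {
  count <- 0L
  for (i in subset) {
    if (s[i] == q[i]) next
    dev <- s
    dev[i] <- q[i]
    u_now <- oracle_payoff(payoffs, i, s)
    u_dev <- oracle_payoff(payoffs, i, dev)
    hit <- if (tie_leq) u_now <= u_dev else u_now < u_dev
    if (hit) count <- count + 1L
  }
  count
}

oracle_verdict <- function(payoffs, s, q, tie_leq = TRUE) {
  kf <- oracle_k(payoffs, s, q, tie_leq)
  kb <- oracle_k(payoffs, q, s, tie_leq)
  if (kf < kb) "ascends" else if (kf > kb) "ascended" else "indifferent"
}

# every strategy profile of the game, as rows
all_profiles <- function(n_strategies) {
  as.matrix(expand.grid(lapply(n_strategies, seq_len)))
}

# exhaustive Nash equilibria: no player has a strictly improving deviation
oracle_ne_set <- function(payoffs, n_strategies) {
  profs <- all_profiles(n_strategies)
  is_ne <- apply(profs, 1L, function(s) {
    for (i in seq_along(s)) {
      u_now <- oracle_payoff(payoffs, i, s)
      for (a in seq_len(n_strategies[i])) {
        if (a == s[i]) next
        dev <- s
        dev[i] <- a
        if (oracle_payoff(payoffs, i, dev) > u_now) return(FALSE)
      }
    }
    TRUE
  })
  profs[is_ne, , drop = FALSE]
}

# exhaustive non-ascended set under the full relation
oracle_nnd_set <- function(payoffs, n_strategies) {
  profs <- all_profiles(n_strategies)
  keep <- apply(profs, 1L, function(s) {
    for (r in seq_len(nrow(profs))) {
      q <- profs[r, ]
      if (oracle_k(payoffs, q, s) < oracle_k(payoffs, s, q)) return(FALSE)
    }
    TRUE
  })
  profs[keep, , drop = FALSE]
}

# exhaustive p-non-ascended set: no q and no subset (any size 1..n) with
# k_p(q, s, I_p) < k_p(s, q, I_p)
oracle_pnnd_set <- function(payoffs, n_strategies) {
  n <- length(n_strategies)
  profs <- all_profiles(n_strategies)
  subsets <- unlist(lapply(seq_len(n), function(sz) {
    m <- utils::combn(n, sz)
    lapply(seq_len(ncol(m)), function(c) m[, c])
  }), recursive = FALSE)
  keep <- apply(profs, 1L, function(s) {
    for (r in seq_len(nrow(profs))) {
      q <- profs[r, ]
      for (sub in subsets) {
        if (oracle_kp(payoffs, q, s, sub) < oracle_kp(payoffs, s, q, sub)) {
          return(FALSE)
        }
      }
    }
    TRUE
  })
  profs[keep, , drop = FALSE]
}

# community fitness from the raw definition: per-node k_in / k_out loops
oracle_fitness <- function(members, edges, alpha = 1) {
  if (length(members) == 0L) return(0)
  num <- 0
  den <- 0
  for (j in members) {
    inc <- edges[edges[, 1L] == j | edges[, 2L] == j, , drop = FALSE]
    other <- ifelse(inc[, 1L] == j, inc[, 2L], inc[, 1L])
    num <- num + sum(other %in% members)
    den <- den + nrow(inc)
  }
  if (den == 0) return(0)
  num / den^alpha
}

# G(n, p) random simple network for property tests
rand_network <- function(n, p_edge = 0.3) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pmneo::network(pairs[keep, , drop = FALSE], n_nodes = n)
}
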