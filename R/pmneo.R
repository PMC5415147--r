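# Internal payoff engine -----------------------------------------------------
#
# Individuals are lists: lab (label vector), budget (fixed label budget
# c_j), L and D (per-label community aggregates: L[w] = sum of internal
# degrees = 2 * internal edge count of community w, D[w] = degree sum), and
# u (payoff of every node under this profile).  With these aggregates a
# node payoff or a unilateral-deviation payoff costs O(deg(i)).

.agg <- function(lab, budget, net) {
  L <- numeric(budget)
  D <- numeric(budget)
  if (net$m > 0L) {
    e1 <- net$edges[, 1L]
    same <- lab[e1] == lab[net$edges[, 2L]]
    L <- 2 * tabulate(lab[e1[same]], nbins = budget)
  }
  rs <- rowsum(net$deg, lab)
  D[as.integer(rownames(rs))] <- rs[, 1L]
  list(L = L, D = D)
}

.payoffs_all <- function(lab, L, D, net, alpha) {
  n <- net$n
  u <- numeric(n)
  if (net$m == 0L) return(u)
  e1 <- net$edges[, 1L]
  e2 <- net$edges[, 2L]
  same <- lab[e1] == lab[e2]
  t_in <- tabulate(c(e1[same], e2[same]), nbins = n)
  Lw <- L[lab]
  Dw <- D[lab]
  f1 <- numeric(n)
  pos <- Dw > 0
  f1[pos] <- Lw[pos] / Dw[pos]^alpha
  d2 <- Dw - net$deg
  f2 <- numeric(n)
  pos <- d2 > 0
  f2[pos] <- (Lw[pos] - 2 * t_in[pos]) / d2[pos]^alpha
  f1 - f2
}

# payoff of node i under individual `ind` (from cached aggregates)
.u_node <- function(i, ind, net, alpha) {
  w <- ind$lab[i]
  t_i <- sum(ind$lab[net$adj[[i]]] == w)
  L <- ind$L[w]
  D <- ind$D[w]
  f1 <- if (D > 0) L / D^alpha else 0
  D2 <- D - net$deg[i]
  f2 <- if (D2 > 0) (L - 2 * t_i) / D2^alpha else 0
  f1 - f2
}

# payoff of node i after unilaterally moving to label v under `ind`
.u_dev <- function(i, v, ind, net, alpha) {
  t_i <- sum(ind$lab[net$adj[[i]]] == v)
  L <- ind$L[v]
  D <- ind$D[v]
  d_i <- net$deg[i]
  f1 <- if (D + d_i > 0) (L + 2 * t_i) / (D + d_i)^alpha else 0
  f2 <- if (D > 0) L / D^alpha else 0
  f1 - f2
}

# move node i to label v, updating aggregates incrementally
.move <- function(ind, i, v, net) {
  w <- ind$lab[i]
  nbr_lab <- ind$lab[net$adj[[i]]]
  d_i <- net$deg[i]
  ind$L[w] <- ind$L[w] - 2 * sum(nbr_lab == w)
  ind$D[w] <- ind$D[w] - d_i
  ind$L[v] <- ind$L[v] + 2 * sum(nbr_lab == v)
  ind$D[v] <- ind$D[v] + d_i
  ind$lab[i] <- v
  ind
}

.new_individual <- function(budget, net, alpha) {
  lab <- sample.int(budget, net$n, replace = TRUE)
  a <- .agg(lab, budget, net)
  list(lab = lab, budget = budget, L = a$L, D = a$D,
       u = .payoffs_all(lab, a$L, a$D, net, alpha))
}

.reevaluate <- function(ind, net, alpha) {
  a <- .agg(ind$lab, ind$budget, net)
  ind$L <- a$L
  ind$D <- a$D
  ind$u <- .payoffs_all(ind$lab, a$L, a$D, net, alpha)
  ind
}

# fast modularity from a label vector (same value as modularity_q())
.q_of <- function(lab, net) {
  e1 <- net$edges[, 1L]
  same <- lab[e1] == lab[net$edges[, 2L]]
  nb <- max(lab)
  L <- 2 * tabulate(lab[e1[same]], nbins = nb)
  D <- numeric(nb)
  rs <- rowsum(net$deg, lab)
  D[as.integer(rownames(rs))] <- rs[, 1L]
  m2 <- 2 * net$m
  sum(L / m2 - (D / m2)^2)
}

# one reduced-ascendancy comparison of offspring vs archive (both on the
# active network); counts every payoff evaluation it performs
.compare <- function(off, arch, net, alpha, p, tie_leq, replace) {
  subset <- sample_player_subset(net$n, p, replace)
  kf <- 0L
  kb <- 0L
  evals <- 0L
  for (i in subset) {
    if (off$lab[i] == arch$lab[i]) next
    u_p <- .u_node(i, off, net, alpha)
    u_pd <- .u_dev(i, arch$lab[i], off, net, alpha)
    u_a <- .u_node(i, arch, net, alpha)
    u_ad <- .u_dev(i, off$lab[i], arch, net, alpha)
    evals <- evals + 4L
    if (tie_leq) {
      if (u_p <= u_pd) kf <- kf + 1L
      if (u_a <= u_ad) kb <- kb + 1L
    } else {
      if (u_p < u_pd) kf <- kf + 1L
      if (u_a < u_ad) kb <- kb + 1L
    }
  }
  list(kf = kf, kb = kb, evals = evals, ascends = kf < kb)
}

# one full population pass (the extremal-optimization iteration)
.eo_pass <- function(pop, arch, net, alpha, p, tie_leq, replace, ell) {
  evals <- 0L
  n <- net$n
  for (j in seq_along(pop)) {
    ind <- pop[[j]]
    # the ell lowest-payoff nodes, payoff ties broken uniformly at random
    sel <- order(ind$u, sample.int(n))[seq_len(min(ell, n))]
    for (i in sel) {
      if (ind$budget <= 1L) break
      v <- sample.int(ind$budget - 1L, 1L)
      if (v >= ind$lab[i]) v <- v + 1L
      ind <- .move(ind, i, v, net)
    }
    ind$u <- .payoffs_all(ind$lab, ind$L, ind$D, net, alpha)
    cmp <- .compare(ind, arch[[j]], net, alpha, p, tie_leq, replace)
    evals <- evals + cmp$evals
    if (cmp$ascends) arch[[j]] <- ind
    pop[[j]] <- ind
  }
  list(pop = pop, arch = arch, evals = evals)
}

# Exported search components -------------------------------------------------

#' Schedule for the number of nodes mutated per iteration
#'
#' The extremal-optimization step reassigns the `ell` worst-payoff nodes of
#' each individual.  `ell` decays linearly from about a tenth of the
#' network size at the first generation down to 1 at the horizon:
#' \deqn{\ell = \max\{1,\ \mathrm{round}(0.1\, n\, (1 - g / G))\}.}
#' Early generations therefore make coarse moves and late generations fine
#' single-node refinements.  [pmneo()] accepts any replacement schedule via
#' its `ell_schedule` argument.
#'
#' @param n number of nodes.
#' @param nr_gen current generation (0-based).
#' @param max_gen total number of generations.
#' @return a positive integer.
#' @examples
#' ell_schedule(128, 0, 500)    # 13
#' ell_schedule(128, 500, 500)  # 1
#' @export
ell_schedule <- function(n, nr_gen, max_gen) {
  stopifnot(nr_gen >= 0, nr_gen <= max_gen)
  max(1L, as.integer(round(0.1 * n * (1 - nr_gen / max_gen))))
}

#' Search parameters for the extremal-optimization search
#'
#' Bundles and validates every knob of [pmneo()].  Defaults follow the
#' standard configuration for community detection: population 50, mixing
#' probability 0.02, 30 generations on the original network alternating
#' with 10 on a mixed one, and a quarter of the population pinned to a
#' designated community count when one is supplied.
#'
#' @param pop_size population size M (the archive has the same size).
#' @param max_gen number of EO generations.
#' @param p fraction of players inspected by the reduced ascendancy
#'   relation, in (0, 1]; `p = 1` gives the full relation.
#' @param rho network-mixing probability: each mixing event performs
#'   `round(rho * m)` degree-preserving double-edge-swap attempts.
#' @param lambda_big,lambda_small generations spent on the original and on
#'   the mixed network per phase cycle.
#' @param c_min,c_max bounds for the per-individual community-count budget.
#' @param pinned_fraction fraction of individuals whose budget is pinned to
#'   `pinned_count` (used when the expected number of communities is known).
#' @param pinned_count the designated community count, or `NULL`.
#' @param tie tie handling in the ascendancy counts, see [k_operator()].
#' @param subset_replace sample comparison subsets with replacement, see
#'   [sample_player_subset()].
#' @param ell_schedule replacement mutation-size schedule
#'   `function(n, nr_gen, max_gen)`, or `NULL` for [ell_schedule()].
#' @return an object of class `"eo_params"`.
#' @export
eo_params <- function(pop_size = 50, max_gen = 500, p = 0.25, rho = 0.02,
                      lambda_big = 30, lambda_small = 10,
                      c_min = 2, c_max = 10,
                      pinned_fraction = 0.25, pinned_count = NULL,
                      tie = c("leq", "strict"), subset_replace = FALSE,
                      ell_schedule = NULL) {
  tie <- match.arg(tie)
  stopifnot(pop_size >= 1, max_gen >= 0, p > 0, p <= 1, rho >= 0,
            lambda_big >= 1, lambda_small >= 1,
            c_min >= 1, c_max >= c_min,
            pinned_fraction >= 0, pinned_fraction <= 1)
  if (!is.null(pinned_count)) {
    stopifnot(pinned_count >= c_min, pinned_count <= c_max)
  }
  structure(
    list(pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
         p = p, rho = rho, lambda_big = as.integer(lambda_big),
         lambda_small = as.integer(lambda_small),
         c_min = as.integer(c_min), c_max = as.integer(c_max),
         pinned_fraction = pinned_fraction,
         pinned_count = if (is.null(pinned_count)) NULL else as.integer(pinned_count),
         tie = tie, subset_replace = subset_replace,
         ell_schedule = ell_schedule),
    class = "eo_params"
  )
}

#' Initialize the search populations
#'
#' Creates the population P and the archive A: each of the `pop_size`
#' paired individuals gets a fixed community-count budget drawn uniformly
#' from `[c_min, c_max]` — except the first
#' `floor(pinned_fraction * pop_size)` pairs, whose budget is pinned to
#' `pinned_count` when one is given — and labels drawn uniformly from its
#' budget.  Population and archive are initialized independently.
#'
#' @param net a [network()].
#' @param params an [eo_params()] object.
#' @param alpha fitness exponent of the community game.
#' @return an object of class `"eo_state"` holding the populations, the
#'   active network, phase bookkeeping and the payoff-evaluation counter.
#' @export
initialize_populations <- function(net, params, alpha = 1) {
  stopifnot(inherits(net, "pmneo_network"), inherits(params, "eo_params"))
  if (params$c_max > net$n) {
    stop("'c_max' cannot exceed the number of nodes", call. = FALSE)
  }
  if (floor(params$p * net$n) < 1) {
    stop("invalid 'p' for this network: n_p = [p * n] must be > 0",
         call. = FALSE)
  }
  M <- params$pop_size
  budgets <- sample(seq.int(params$c_min, params$c_max), M, replace = TRUE)
  if (!is.null(params$pinned_count)) {
    n_pin <- floor(params$pinned_fraction * M)
    if (n_pin > 0) budgets[seq_len(n_pin)] <- params$pinned_count
  }
  pop <- lapply(budgets, .new_individual, net = net, alpha = alpha)
  arch <- lapply(budgets, .new_individual, net = net, alpha = alpha)
  structure(
    list(pop = pop, arch = arch, generation = 0L,
         phase = "original", phase_counter = 0L,
         net_original = net, net_active = net,
         alpha = alpha, evals = 0, params = params),
    class = "eo_state"
  )
}

#' Run one extremal-optimization generation
#'
#' For every individual \eqn{P_j}: the `ell` nodes with the lowest payoffs
#' are each reassigned a different random community from \eqn{P_j}'s label
#' budget, giving the offspring \eqn{P_j'}; if \eqn{P_j'} p-Nash ascends
#' the paired archive member \eqn{A_j} under a freshly drawn player subset,
#' \eqn{A_j} is replaced; \eqn{P_j} is always replaced by its offspring.
#' Payoffs are evaluated on the state's *active* network.  Phase switching
#' (network mixing) is handled by [pmneo()], not here.
#'
#' @param state an [initialize_populations()] state.
#' @param ell number of nodes to mutate per individual; defaults to the
#'   state's schedule at its current generation.
#' @return the updated `"eo_state"` (generation advanced by one).
#' @export
eo_iteration <- function(state, ell = NULL) {
  stopifnot(inherits(state, "eo_state"))
  params <- state$params
  if (is.null(ell)) {
    sched <- params$ell_schedule
    if (is.null(sched)) sched <- ell_schedule
    ell <- sched(state$net_active$n, state$generation, max(1L, params$max_gen))
  }
  res <- .eo_pass(state$pop, state$arch, state$net_active, state$alpha,
                  params$p, params$tie == "leq", params$subset_replace, ell)
  state$pop <- res$pop
  state$arch <- res$arch
  state$evals <- state$evals + res$evals
  state$generation <- state$generation + 1L
  state$phase_counter <- state$phase_counter + 1L
  state
}

#' Degree-preserving network mixing
#'
#' The diversity mechanism of the search: `round(rho * m)` double-edge-swap
#' attempts are made, each picking two distinct edges (a,b) and (c,d),
#' deleting them and reconnecting the four endpoints in one of the two
#' alternative pairings.  Attempts that would create a self-loop or a
#' duplicate edge are rejected, so the mixed network is again simple and
#' every node keeps its exact degree.
#'
#' @param net a [network()] with at least one edge.
#' @param rho mixing probability controlling the magnitude of the change.
#' @return a new `pmneo_network` with the same degree sequence.
#' @examples
#' g <- generate_gn(3)$network
#' mixed <- mix_network(g, 0.02)
#' identical(mixed$deg, g$deg)
#' @export
mix_network <- function(net, rho) {
  stopifnot(inherits(net, "pmneo_network"), rho >= 0)
  n_try <- round(rho * net$m)
  if (n_try < 1 || net$m < 2L) return(net)
  edges <- net$edges
  key <- function(a, b) (pmin(a, b) - 1) * as.double(net$n) + pmax(a, b)
  keys <- key(edges[, 1L], edges[, 2L])
  for (att in seq_len(n_try)) {
    ij <- sample.int(net$m, 2L)
    a <- edges[ij[1L], 1L]; b <- edges[ij[1L], 2L]
    c_ <- edges[ij[2L], 1L]; d <- edges[ij[2L], 2L]
    # the two alternative pairings of the four endpoints
    if (stats::runif(1) < 0.5) {
      new1 <- c(a, d); new2 <- c(c_, b)
    } else {
      new1 <- c(a, c_); new2 <- c(b, d)
    }
    if (new1[1L] == new1[2L] || new2[1L] == new2[2L]) next
    k1 <- key(new1[1L], new1[2L]); k2 <- key(new2[1L], new2[2L])
    if (k1 == k2 || k1 %in% keys || k2 %in% keys) next
    edges[ij[1L], ] <- sort(new1)
    edges[ij[2L], ] <- sort(new2)
    keys[ij] <- c(k1, k2)
  }
  network(edges, n_nodes = net$n)
}

# Main fitting function -------------------------------------------------------

#' Detect community structure by p-Nash extremal optimization
#'
#' Approximates a Nash equilibrium of the community detection game: every
#' node is a player whose payoff is its marginal contribution to its
#' community's fitness, and a partition in which no node gains by switching
#' community is taken as the community structure.  The search evolves a
#' population of candidate partitions with extremal optimization — each
#' generation the worst-payoff nodes of each individual are randomly
#' reassigned — and an archive keeps each individual's best partition so
#' far under the reduced p-Nash ascendancy relation, which compares two
#' partitions on a random subset of `[p * n]` players only.  Every
#' `lambda_big` generations the search moves to a degree-preserving
#' randomly mixed copy of the network for `lambda_small` generations as a
#' diversity mechanism; at each switch the archive is re-initialized and
#' all payoffs are re-evaluated on the newly active network.  The reported
#' partition is the archive member with the highest modularity on the
#' *original* network; modularity never guides the search itself.
#'
#' @param net a [network()] (or anything [as_network()] accepts) with at
#'   least one edge.
#' @param c_min,c_max community-count bounds; individuals search for a
#'   fixed count drawn from this range.  Set them to bracket the number of
#'   communities you expect.
#' @param p fraction of players inspected per comparison, in (0, 1]; small
#'   values cut payoff evaluations roughly proportionally with little loss
#'   in solution quality.
#' @param max_gen number of EO generations.
#' @param pop_size population (and archive) size.
#' @param pinned_count optional community count assigned to a
#'   `pinned_fraction` share of the population.
#' @param alpha community-fitness exponent.
#' @param seed optional integer seed; a run is fully reproducible from
#'   (seed, parameters).
#' @param trace record the per-generation best modularity (small cost;
#'   disable for long runs on large networks).
#' @inheritParams eo_params
#' @param ... further arguments passed to [eo_params()].
#' @return an object of class `"pmneo"` with elements `membership` (integer
#'   labels renumbered to 1..k), `modularity`, `n_communities`,
#'   `eval_count` (payoff evaluations performed inside ascendancy
#'   comparisons), `diagnostics` (per-generation data frame with the best
#'   archive modularity, cumulative evaluation count and phase),
#'   `params`, `seed` and `network`.
#' @seealso [summary.pmneo()] for the equilibrium check of the fitted
#'   partition, [nmi()] to score it against a reference partition.
#' @examples
#' fit <- pmneo(demo_network7(), c_min = 2, c_max = 3, p = 0.5,
#'              max_gen = 60, pop_size = 10, seed = 1)
#' fit$membership
#' @export
pmneo <- function(net, c_min = 2, c_max = 10, p = 0.25, max_gen = 500,
                  pop_size = 50, pinned_count = NULL, alpha = 1,
                  seed = NULL, trace = TRUE, ...) {
  net <- as_network(net)
  if (net$m < 1L) stop("the network must have at least one edge", call. = FALSE)
  params <- eo_params(pop_size = pop_size, max_gen = max_gen, p = p,
                      c_min = c_min, c_max = c_max,
                      pinned_count = pinned_count, ...)
  if (!is.null(seed)) set.seed(seed)
  state <- initialize_populations(net, params, alpha = alpha)
  sched <- params$ell_schedule
  if (is.null(sched)) sched <- ell_schedule
  gens <- params$max_gen
  diag_q <- if (trace) numeric(gens) else NULL
  diag_evals <- if (trace) numeric(gens) else NULL
  diag_phase <- if (trace) character(gens) else NULL
  for (g in seq_len(gens)) {
    ell <- sched(net$n, state$generation, gens)
    state <- eo_iteration(state, ell = ell)
    if (trace) {
      diag_q[g] <- max(vapply(state$arch, function(a) .q_of(a$lab, net),
                              numeric(1)))
      diag_evals[g] <- state$evals
      diag_phase[g] <- state$phase
    }
    # phase switching (diversity mechanism)
    if (state$phase == "original" &&
        state$phase_counter >= params$lambda_big && g < gens) {
      state$net_active <- mix_network(net, params$rho)
      state$phase <- "mixed"
      state$phase_counter <- 0L
      state$arch <- lapply(vapply(state$arch, `[[`, integer(1), "budget"),
                           .new_individual, net = state$net_active,
                           alpha = alpha)
      state$pop <- lapply(state$pop, .reevaluate, net = state$net_active,
                          alpha = alpha)
    } else if (state$phase == "mixed" &&
               state$phase_counter >= params$lambda_small && g < gens) {
      state$net_active <- net
      state$phase <- "original"
      state$phase_counter <- 0L
      state$arch <- lapply(vapply(state$arch, `[[`, integer(1), "budget"),
                           .new_individual, net = net, alpha = alpha)
      state$pop <- lapply(state$pop, .reevaluate, net = net, alpha = alpha)
    }
  }
  qs <- vapply(state$arch, function(a) .q_of(a$lab, net), numeric(1))
  best <- which.max(qs)
  lab <- state$arch[[best]]$lab
  membership <- match(lab, unique(lab))  # renumber to consecutive 1..k
  out <- list(
    membership = membership,
    modularity = qs[best],
    n_communities = length(unique(membership)),
    eval_count = state$evals,
    diagnostics = if (trace) {
      data.frame(generation = seq_len(gens), best_q = diag_q,
                 evals = diag_evals, phase = diag_phase)
    } else NULL,
    params = params, alpha = alpha, seed = seed, network = net,
    call = match.call()
  )
  class(out) <- "pmneo"
  out
}

#' @export
print.pmneo <- function(x, ...) {
  cat("p-Nash extremal-optimization community detection\n")
  cat(sprintf("  %d nodes, %d edges; p = %g, %d generations, population %d\n",
              x$network$n, x$network$m, x$params$p, x$params$max_gen,
              x$params$pop_size))
  cat(sprintf("  communities: %d   modularity Q = %.4f\n",
              x$n_communities, x$modularity))
  cat(sprintf("  payoff evaluations in ascendancy comparisons: %d\n",
              as.integer(x$eval_count)))
  invisible(x)
}

#' Summarize a fitted community structure
#'
#' Reports community sizes and runs the exhaustive equilibrium check on the
#' fitted partition: the fraction of nodes that could strictly improve
#' their payoff by any unilateral community change (labels present in the
#' partition plus one empty community).  A fraction of 0 means the
#' partition is a Nash equilibrium of the community game.
#'
#' @param object a [pmneo()] fit.
#' @param ... unused.
#' @return an object of class `"summary.pmneo"`.
#' @export
summary.pmneo <- function(object, ...) {
  game <- community_game(object$network, alpha = object$alpha)
  eq <- verify_equilibrium(object$membership, game)
  out <- list(fit = object, sizes = table(object$membership),
              equilibrium = eq)
  class(out) <- "summary.pmneo"
  out
}

#' @export
print.summary.pmneo <- function(x, ...) {
  print(x$fit)
  cat("  community sizes:", paste(as.integer(x$sizes), collapse = ", "), "\n")
  cat(sprintf("  improving-node fraction: %.4f%s\n", x$equilibrium$fraction,
              if (x$equilibrium$fraction == 0) " (Nash equilibrium)" else ""))
  invisible(x)
}

#' Plot the search trace
#'
#' Shows the best archive modularity per generation; generations run on a
#' mixed network are marked along the axis.
#'
#' @param x a [pmneo()] fit created with `trace = TRUE`.
#' @param ... passed to [plot()].
#' @export
plot.pmneo <- function(x, ...) {
  d <- x$diagnostics
  if (is.null(d)) stop("fit was run with trace = FALSE", call. = FALSE)
  plot(d$generation, d$best_q, type = "l", xlab = "generation",
       ylab = "best archive modularity Q", ...)
  mixed <- d$generation[d$phase == "mixed"]
  if (length(mixed)) graphics::rug(mixed, col = "grey60")
  invisible(x)
}

#' Write a run report
#'
#' Serializes a fit as structured text: a key-value header (seed,
#' parameters, best modularity, improving-node fraction, evaluation count
#' and, when a reference partition is given, the normalized mutual
#' information against it) followed by the per-generation trace table.
#'
#' @param fit a [pmneo()] fit.
#' @param path output file.
#' @param truth optional reference partition for an NMI line.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(fit, path, truth = NULL) {
  stopifnot(inherits(fit, "pmneo"))
  eq <- verify_equilibrium(fit$membership,
                           community_game(fit$network, alpha = fit$alpha))
  lines <- c(
    paste("seed", if (is.null(fit$seed)) "NA" else fit$seed),
    paste("n_nodes", fit$network$n),
    paste("m_edges", fit$network$m),
    paste("p", fit$params$p),
    paste("pop_size", fit$params$pop_size),
    paste("max_gen", fit$params$max_gen),
    paste("rho", fit$params$rho),
    paste("lambda_big", fit$params$lambda_big),
    paste("lambda_small", fit$params$lambda_small),
    paste("c_min", fit$params$c_min),
    paste("c_max", fit$params$c_max),
    paste("n_communities", fit$n_communities),
    paste("modularity", format(fit$modularity, digits = 10)),
    paste("improving_fraction", format(eq$fraction, digits = 10)),
    paste("payoff_evaluations", as.integer(fit$eval_count))
  )
  if (!is.null(truth)) {
    lines <- c(lines, paste("nmi", format(nmi(fit$membership, truth),
                                          digits = 10)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  if (!is.null(fit$diagnostics)) {
    writeLines("", con)
    utils::write.table(fit$diagnostics, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
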