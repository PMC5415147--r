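#' Community fitness
#'
#' The fitness of a node set \eqn{C} is the ratio of its total internal
#' degree to its total degree raised to the exponent \eqn{\alpha}:
#' \deqn{f(C) = \frac{\sum_{j \in C} k^{in}_j}
#'                   {\left(\sum_{j \in C} (k^{in}_j + k^{out}_j)\right)^\alpha},}
#' where \eqn{k^{in}_j} counts links from \eqn{j} to other members of
#' \eqn{C} and \eqn{k^{out}_j} links from \eqn{j} to non-members.  With
#' \eqn{\alpha = 1} (the default used throughout the search) the fitness is
#' the fraction of the member nodes' link ends that stay inside the set, so
#' \eqn{f(C) \in [0, 1]}.  The empty set, and any set whose members are all
#' isolated, have fitness 0 by convention (the continuous limit of a zero
#' numerator).
#'
#' @param members integer vector of node IDs.
#' @param net a [network()].
#' @param alpha positive exponent controlling how strongly large communities
#'   are penalised; the community game uses 1.
#' @return a single numeric fitness value.
#' @examples
#' net <- demo_network7()
#' community_fitness(c(1, 2, 3), net)      # 6/7
#' community_fitness(c(4, 5, 6, 7), net)   # 12/13
#' @export
community_fitness <- function(members, net, alpha = 1) {
  stopifnot(inherits(net, "pmneo_network"), alpha > 0)
  members <- as.integer(members)
  if (anyNA(members) || any(members < 1L) || any(members > net$n)) {
    stop("member IDs must be nodes of the network", call. = FALSE)
  }
  if (length(members) == 0L) return(0)
  inset <- logical(net$n)
  inset[members] <- TRUE
  denom <- sum(net$deg[members])
  if (denom == 0) return(0)
  both_in <- inset[net$edges[, 1L]] & inset[net$edges[, 2L]]
  num <- 2 * sum(both_in)  # each internal edge contributes 2 to sum(k_in)
  num / denom^alpha
}

#' Node payoff in the community game
#'
#' The payoff of node `i` under a community assignment is its marginal
#' contribution to its own community \eqn{C_w}:
#' \deqn{u_i(s) = f(C_w \cup \{i\}) - f(C_w \setminus \{i\}),\quad w = s_i.}
#'
#' @param i node ID.
#' @param profile integer community label vector of length `net$n`.
#' @param net a [network()].
#' @param alpha fitness exponent, see [community_fitness()].
#' @return numeric payoff.
#' @examples
#' net <- demo_network7()
#' node_payoff(3, c(1, 1, 1, 2, 2, 2, 2), net)  # 5/14
#' @export
node_payoff <- function(i, profile, net, alpha = 1) {
  stopifnot(inherits(net, "pmneo_network"))
  i <- as.integer(i)
  profile <- as.integer(profile)
  if (length(profile) != net$n) {
    stop("profile length must equal the number of nodes", call. = FALSE)
  }
  if (is.na(i) || i < 1L || i > net$n) stop("invalid node ID", call. = FALSE)
  own <- which(profile == profile[i])
  community_fitness(own, net, alpha) -
    community_fitness(setdiff(own, i), net, alpha)
}

#' Payoff after a unilateral community change
#'
#' Evaluates \eqn{u_i(q_i, s_{-i})}: the payoff node `i` would receive if it
#' alone switched to community `new_label` while everyone else kept their
#' label.  Only the target community's aggregates are evaluated (the node's
#' old community does not enter its post-move payoff); the rest of the
#' partition is never re-scored.
#'
#' @inheritParams node_payoff
#' @param new_label the community label `i` deviates to; if equal to the
#'   node's current label this reduces to [node_payoff()].
#' @return numeric payoff of `i` after the move.
#' @export
deviation_payoff <- function(i, new_label, profile, net, alpha = 1) {
  stopifnot(inherits(net, "pmneo_network"))
  i <- as.integer(i)
  new_label <- as.integer(new_label)
  profile <- as.integer(profile)
  if (length(profile) != net$n) {
    stop("profile length must equal the number of nodes", call. = FALSE)
  }
  if (is.na(i) || i < 1L || i > net$n) stop("invalid node ID", call. = FALSE)
  if (new_label == profile[i]) return(node_payoff(i, profile, net, alpha))
  target <- which(profile == new_label)
  target <- target[target != i]
  d_i <- net$deg[i]
  t_i <- sum(profile[net$adj[[i]]] == new_label)
  # aggregates of the target community without i
  L <- 0
  D <- sum(net$deg[target])
  if (length(target)) {
    inset <- logical(net$n)
    inset[target] <- TRUE
    L <- 2 * sum(inset[net$edges[, 1L]] & inset[net$edges[, 2L]])
  }
  f_with <- if (D + d_i > 0) (L + 2 * t_i) / (D + d_i)^alpha else 0
  f_without <- if (D > 0) L / D^alpha else 0
  f_with - f_without
}

#' Modularity of a partition
#'
#' Newman's modularity
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{d_i d_j}{2m}\right)
#'           \delta(C_i, C_j),}
#' with the sum over all ordered node pairs including \eqn{i = j}.  In the
#' search, modularity is never used to guide the optimization; it only
#' selects which archive member is reported.
#'
#' @inheritParams node_payoff
#' @return numeric modularity, at most 1; 0 for the single-community
#'   partition.
#' @examples
#' tri2 <- network(rbind(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))
#' modularity_q(c(1, 1, 1, 2, 2, 2), tri2)  # 0.5
#' @export
modularity_q <- function(profile, net) {
  stopifnot(inherits(net, "pmneo_network"))
  if (net$m < 1L) stop("modularity is undefined for an edgeless network",
                       call. = FALSE)
  profile <- as.integer(profile)
  if (length(profile) != net$n) {
    stop("profile length must equal the number of nodes", call. = FALSE)
  }
  f <- factor(profile)
  same <- profile[net$edges[, 1L]] == profile[net$edges[, 2L]]
  # per-community: 2 * internal edges and degree sum
  L <- as.numeric(tapply(c(net$edges[same, 1L]), factor(profile[net$edges[same, 1L]], levels = levels(f)), length))
  L[is.na(L)] <- 0
  L <- 2 * L
  D <- as.numeric(tapply(net$deg, f, sum))
  D[is.na(D)] <- 0
  m2 <- 2 * net$m
  sum(L / m2 - (D / m2)^2)
}
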