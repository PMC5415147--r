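#' Girvan-Newman planted-partition benchmark
#'
#' Generates the classical synthetic community-detection benchmark: 128
#' nodes in four planted communities of 32, expected node degree 16, with
#' `z_out` of each node's links expected to leave its community.  It is
#' realized as an independent-edge planted-partition model: intra-community
#' pairs are linked with probability
#' \eqn{(d - z_{out}) / (c - 1)} and inter-community pairs with probability
#' \eqn{z_{out} / (n - c)} (defaults: \eqn{(16 - z_{out})/31} and
#' \eqn{z_{out}/96}), which gives the stated expected degrees.  Networks
#' with `z_out` up to about 5 have a clear structure; `z_out = 8` puts half
#' of each node's links outside its community and is the hardest setting.
#'
#' @param z_out expected number of inter-community links per node,
#'   `0 <= z_out < expected_degree`.
#' @param n_communities number of planted communities.
#' @param community_size nodes per community.
#' @param expected_degree expected node degree.
#' @return a list with `network` (a [network()]) and `membership` (the
#'   planted labels, blocks of `community_size` consecutive nodes).
#' @examples
#' gn <- generate_gn(3)
#' gn$network
#' table(gn$membership)
#' @export
generate_gn <- function(z_out, n_communities = 4, community_size = 32,
                        expected_degree = 16) {
  stopifnot(z_out >= 0, z_out < expected_degree,
            n_communities >= 2, community_size >= 2)
  n <- n_communities * community_size
  p_in <- (expected_degree - z_out) / (community_size - 1)
  p_out <- z_out / (n - community_size)
  stopifnot(p_in <= 1, p_out <= 1)
  membership <- rep(seq_len(n_communities), each = community_size)
  # all unordered pairs, Bernoulli-linked with the block probability
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  p_edge <- ifelse(membership[pair_i] == membership[pair_j], p_in, p_out)
  keep <- stats::runif(length(p_edge)) < p_edge
  net <- network(cbind(pair_i[keep], pair_j[keep]), n_nodes = n)
  list(network = net, membership = membership)
}

#' Normalized mutual information between two partitions
#'
#' Measures the agreement of two partitions of the same node set through
#' their confusion matrix \eqn{N}:
#' \deqn{NMI = \frac{-2 \sum_{ij} N_{ij}
#'        \log\frac{N_{ij} N}{N_{i\cdot} N_{\cdot j}}}
#'       {\sum_i N_{i\cdot}\log\frac{N_{i\cdot}}{N} +
#'        \sum_j N_{\cdot j}\log\frac{N_{\cdot j}}{N}}.}
#' This is the mutual information normalized by the average of the two
#' partition entropies; 1 means the partitions are identical up to label
#' permutation, 0 means they are independent.  When both partitions are
#' single-community (both entropies zero) the value is defined as 1.
#' `variant = "max"` normalizes by the larger entropy instead.
#'
#' @param a,b integer label vectors of equal length.
#' @param variant entropy normalization: `"mean"` (default) or `"max"`.
#' @return a number in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, labels swapped
#' @export
nmi <- function(a, b, variant = c("mean", "max")) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) {
    stop("partitions must have the same length", call. = FALSE)
  }
  n <- length(a)
  conf <- table(a, b)
  ni <- rowSums(conf)
  nj <- colSums(conf)
  nz <- conf > 0
  mi <- sum(conf[nz] * log(conf[nz] * n / outer(ni, nj)[nz]))
  ha <- -sum(ni[ni > 0] * log(ni[ni > 0] / n))
  hb <- -sum(nj[nj > 0] * log(nj[nj > 0] / n))
  if (ha + hb == 0) return(1)  # both partitions trivial
  if (variant == "mean") 2 * mi / (ha + hb) else mi / max(ha, hb)
}

#' Batch equilibrium check over a set of solutions
#'
#' Applies [verify_equilibrium()] to each (network, partition) pair under
#' the community game and aggregates the improving-node fractions: mean,
#' standard deviation, minimum and normal-approximation 95% confidence
#' limits of the mean.  A mean of 0 indicates that every reported solution
#' is a Nash equilibrium of its game.
#'
#' @param runs list of `list(network = , profile = )` pairs (a [pmneo()]
#'   fit is also accepted: its network and membership are used).
#' @param alpha community-fitness exponent.
#' @param strict see [verify_equilibrium()].
#' @return an object of class `"batch_summary"`: a list with `records`
#'   (per-run data frame with the improving fraction and modularity) and
#'   `aggregates` (named vector: mean, sd, min, cl_lower, cl_upper).
#' @export
improving_fraction_batch <- function(runs, alpha = 1, strict = TRUE) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  frac <- numeric(length(runs))
  qval <- numeric(length(runs))
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    if (inherits(run, "pmneo")) {
      run <- list(network = run$network, profile = run$membership)
    }
    net <- as_network(run$network)
    eq <- verify_equilibrium(run$profile, community_game(net, alpha = alpha),
                             strict = strict)
    frac[r] <- eq$fraction
    qval[r] <- modularity_q(run$profile, net)
  }
  k <- length(frac)
  m <- mean(frac)
  s <- stats::sd(frac)
  if (is.na(s)) s <- 0  # single run
  half <- 1.96 * s / sqrt(k)
  structure(
    list(records = data.frame(run = seq_len(k), improving_fraction = frac,
                              modularity = qval),
         aggregates = c(mean = m, sd = s, min = min(frac),
                        cl_lower = m - half, cl_upper = m + half)),
    class = "batch_summary"
  )
}

#' @export
print.batch_summary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(
    "Improving-node fraction over %d run(s): %.2f +/- %.2f (min %.2f, 95%% CL of mean %.2f %.2f)\n",
    nrow(x$records), a["mean"], a["sd"], a["min"], a["cl_lower"],
    a["cl_upper"]))
  invisible(x)
}

#' Rank-sum comparison of two sets of scores
#'
#' Thin convenience wrapper around [stats::wilcox.test()] for comparing
#' per-run scores (NMI, distances, evaluation counts) between two method
#' configurations, as is customary when benchmarking community detection
#' methods.  The statistics are entirely delegated to the standard
#' rank-sum routine; nothing bespoke is computed here.
#'
#' @param x,y numeric score vectors.
#' @param alpha significance level for the returned rejection flag.
#' @param ... passed to [stats::wilcox.test()].
#' @return a list with `p_value`, `reject` (logical, `p_value < alpha`)
#'   and the underlying `htest` object.
#' @export
compare_scores_ranksum <- function(x, y, alpha = 0.05, ...) {
  ht <- suppressWarnings(stats::wilcox.test(x, y, ...))
  list(p_value = ht$p.value, reject = ht$p.value < alpha, test = ht)
}
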