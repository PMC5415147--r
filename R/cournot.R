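#' Cournot oligopoly game
#'
#' A standard continuous benchmark with a known equilibrium: `n` firms
#' simultaneously choose production quantities \eqn{q_i}; the market
#' clearing price is linear and truncated at zero,
#' \eqn{P(Q) = \max(a - Q, 0)} with \eqn{Q = \sum_i q_i}; marginal cost is
#' constant at `c < a`; and each firm's payoff is its profit
#' \eqn{u_i = q_i P(Q) - c\, q_i}.  The game has a unique symmetric Nash
#' equilibrium \eqn{q_i = (a - c) / (n + 1)}.
#'
#' @param n_firms number of firms.
#' @param a demand intercept.
#' @param c constant marginal cost, `c < a`.
#' @param bounds closed interval of admissible quantities for every firm.
#' @return an object of class `"cournot_params"`.
#' @export
cournot_params <- function(n_firms, a = 24, c = 9, bounds = c(0, 10)) {
  stopifnot(n_firms >= 1, c < a, length(bounds) == 2L, bounds[1] < bounds[2],
            bounds[1] >= 0)
  structure(list(n_firms = as.integer(n_firms), a = a, c = c,
                 bounds = as.numeric(bounds)),
            class = "cournot_params")
}

#' @rdname cournot_params
#' @param quantities numeric vector of produced quantities, one per firm.
#' @param params a [cournot_params()] object.
#' @return [cournot_payoffs()] returns the numeric profit vector.
#' @examples
#' cournot_payoffs(c(5, 5), cournot_params(2))  # 25 25
#' @export
cournot_payoffs <- function(quantities, params) {
  stopifnot(inherits(params, "cournot_params"))
  if (length(quantities) != params$n_firms) {
    stop("one quantity per firm is required", call. = FALSE)
  }
  if (any(quantities < 0)) stop("quantities must be nonnegative", call. = FALSE)
  price <- max(params$a - sum(quantities), 0)
  quantities * price - params$c * quantities
}

#' @rdname cournot_params
#' @return [cournot_ne()] returns the symmetric Nash equilibrium profile
#'   `rep((a - c) / (n + 1), n)`.
#' @examples
#' cournot_ne(cournot_params(10))  # each 15/11
#' @export
cournot_ne <- function(params) {
  stopifnot(inherits(params, "cournot_params"))
  rep((params$a - params$c) / (params$n_firms + 1), params$n_firms)
}

#' @rdname cournot_params
#' @return [cournot_game()] wraps the oligopoly as a continuous
#'   [nash_game]; its best-response map is
#'   \eqn{(a - c - Q_{-i}) / 2} clamped to the bounds.
#' @export
cournot_game <- function(params) {
  stopifnot(inherits(params, "cournot_params"))
  a <- params$a
  cc <- params$c
  bounds <- params$bounds
  new_nash_game(
    n_players = params$n_firms,
    payoff = function(i, s) s[i] * max(a - sum(s), 0) - cc * s[i],
    deviation_payoff = function(i, qi, s) {
      qi * max(a - (sum(s) - s[i] + qi), 0) - cc * qi
    },
    best_response = function(i, s) {
      min(max((a - cc - (sum(s) - s[i])) / 2, bounds[1L]), bounds[2L])
    },
    validate_profile = function(s) {
      if (any(s < bounds[1L] | s > bounds[2L])) {
        stop("quantity outside the strategy bounds", call. = FALSE)
      }
    },
    label = "Cournot oligopoly"
  )
}

#' Extremal-optimization search on the Cournot oligopoly
#'
#' The continuous-strategy variant of the search, without the
#' network-mixing diversity phases (convergence to local equilibria is not
#' an issue in this game).  Each generation, for every individual, the
#' `ell` firms with the lowest profits are mutated — by default redrawn
#' uniformly from the strategy bounds, optionally perturbed by Gaussian
#' noise — and the offspring replaces the paired archive member when it
#' p-Nash ascends it under a freshly drawn firm subset.  Since the
#' equilibrium is known in closed form, the run records the Euclidean
#' distance of the closest archive member to it at every generation.
#'
#' @param params a [cournot_params()] object.
#' @param pop_size population (and archive) size.
#' @param max_gen number of generations; 0 returns the random
#'   initialization.
#' @param p fraction of firms inspected per ascendancy comparison.
#' @param mutation `"uniform"` (fresh draw from the bounds, default) or
#'   `"gaussian"` (perturbation with standard deviation `sd`, clamped to
#'   the bounds).
#' @param sd standard deviation of the Gaussian mutation.
#' @param tie tie handling in the ascendancy counts, see [k_operator()].
#' @param seed optional integer seed.
#' @return an object of class `"pmneo_minus"` with elements `best`
#'   (archive profile closest to the equilibrium), `distance` (its
#'   Euclidean distance to the closed-form equilibrium),
#'   `initial_distance` (the same quantity at initialization), `trace`
#'   (two-column data frame: generation, distance), `eval_count`, `params`
#'   and `seed`.
#' @examples
#' run <- pmneo_minus(cournot_params(10), max_gen = 200, seed = 1)
#' run$distance
#' @export
pmneo_minus <- function(params, pop_size = 10, max_gen = 2000, p = 0.25,
                        mutation = c("uniform", "gaussian"), sd = 0.5,
                        tie = c("leq", "strict"), seed = NULL) {
  stopifnot(inherits(params, "cournot_params"))
  mutation <- match.arg(mutation)
  tie <- match.arg(tie)
  tie_leq <- tie == "leq"
  n <- params$n_firms
  if (floor(p * n) < 1) {
    stop("invalid 'p': n_p = [p * n] must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- params$a
  cc <- params$c
  lo <- params$bounds[1L]
  hi <- params$bounds[2L]
  ne <- cournot_ne(params)
  payoffs_of <- function(x) x * max(a - sum(x), 0) - cc * x
  pop <- replicate(pop_size, stats::runif(n, lo, hi), simplify = FALSE)
  arch <- replicate(pop_size, stats::runif(n, lo, hi), simplify = FALSE)
  pop_u <- lapply(pop, payoffs_of)
  dist_to_ne <- function(xs) {
    min(vapply(xs, function(x) sqrt(sum((x - ne)^2)), numeric(1)))
  }
  trace <- data.frame(generation = integer(0), distance = numeric(0))
  d_init <- dist_to_ne(arch)
  evals <- 0
  for (g in seq_len(max_gen)) {
    ell <- ell_schedule(n, g - 1L, max_gen)
    for (j in seq_len(pop_size)) {
      x <- pop[[j]]
      sel <- order(pop_u[[j]], sample.int(n))[seq_len(min(ell, n))]
      if (mutation == "uniform") {
        x[sel] <- stats::runif(length(sel), lo, hi)
      } else {
        x[sel] <- pmin(pmax(x[sel] + stats::rnorm(length(sel), 0, sd), lo), hi)
      }
      # reduced ascendancy comparison against the archive member
      subset <- sample_player_subset(n, p)
      y <- arch[[j]]
      kf <- 0L
      kb <- 0L
      Qx <- sum(x)
      Qy <- sum(y)
      for (i in subset) {
        if (x[i] == y[i]) next
        u_x <- x[i] * max(a - Qx, 0) - cc * x[i]
        u_xd <- y[i] * max(a - (Qx - x[i] + y[i]), 0) - cc * y[i]
        u_y <- y[i] * max(a - Qy, 0) - cc * y[i]
        u_yd <- x[i] * max(a - (Qy - y[i] + x[i]), 0) - cc * x[i]
        evals <- evals + 4
        if (tie_leq) {
          if (u_x <= u_xd) kf <- kf + 1L
          if (u_y <= u_yd) kb <- kb + 1L
        } else {
          if (u_x < u_xd) kf <- kf + 1L
          if (u_y < u_yd) kb <- kb + 1L
        }
      }
      if (kf < kb) arch[[j]] <- x
      pop[[j]] <- x
      pop_u[[j]] <- payoffs_of(x)
    }
    trace[g, ] <- list(g, dist_to_ne(arch))
  }
  d_arch <- vapply(arch, function(x) sqrt(sum((x - ne)^2)), numeric(1))
  best <- which.min(d_arch)
  structure(
    list(best = arch[[best]], distance = d_arch[best], trace = trace,
         initial_distance = d_init,
         eval_count = evals, params = params, pop_size = pop_size,
         max_gen = max_gen, p = p, seed = seed),
    class = "pmneo_minus"
  )
}

#' @export
print.pmneo_minus <- function(x, ...) {
  cat(sprintf(
    "Cournot extremal optimization: %d firms, p = %g, %d generations\n",
    x$params$n_firms, x$p, x$max_gen))
  cat(sprintf("  distance of best archive member to Nash equilibrium: %.6g\n",
              x$distance))
  invisible(x)
}

#' @export
plot.pmneo_minus <- function(x, ...) {
  if (!nrow(x$trace)) stop("no generations were run", call. = FALSE)
  plot(x$trace$generation, x$trace$distance, type = "l", log = "y",
       xlab = "generation", ylab = "distance to Nash equilibrium", ...)
  invisible(x)
}
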