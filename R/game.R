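#' Game interfaces
#'
#' The ascendancy operators and the equilibrium checker only need four
#' things from a game: the number of players, a payoff function
#' \eqn{u_i(s)}, a unilateral-deviation payoff \eqn{u_i(q_i, s_{-i})}, and
#' either an enumeration of each player's alternative strategies (finite
#' games) or a best-response map (continuous games).  A game object is a
#' list of class `"nash_game"` holding exactly these, so any game — the
#' community game, a payoff table, an oligopoly — plugs into the same
#' machinery.
#'
#' @name nash_game
#' @param n_players number of players.
#' @param payoff `function(i, s)` returning player `i`'s payoff under
#'   profile `s`.
#' @param deviation_payoff `function(i, qi, s)` returning
#'   \eqn{u_i(q_i, s_{-i})}; defaults to substituting `qi` into `s` and
#'   calling `payoff`.
#' @param enumerate_deviations `function(i, s)` returning the alternative
#'   strategies of player `i` (finite games), or `NULL`.
#' @param best_response `function(i, s)` returning player `i`'s best reply
#'   to `s[-i]` (continuous games), or `NULL`.
#' @param validate_profile `function(s)` used for input checking, or `NULL`.
#' @return an object of class `"nash_game"`.
NULL

new_nash_game <- function(n_players, payoff, deviation_payoff = NULL,
                          enumerate_deviations = NULL, best_response = NULL,
                          validate_profile = NULL, label = "game") {
  if (is.null(deviation_payoff)) {
    deviation_payoff <- function(i, qi, s) {
      s[i] <- qi
      payoff(i, s)
    }
  }
  structure(
    list(n_players = as.integer(n_players), payoff = payoff,
         deviation_payoff = deviation_payoff,
         enumerate_deviations = enumerate_deviations,
         best_response = best_response,
         validate_profile = validate_profile, label = label),
    class = "nash_game"
  )
}

#' @export
print.nash_game <- function(x, ...) {
  kind <- if (is.null(x$enumerate_deviations)) "continuous" else "finite"
  cat(sprintf("<nash_game: %s, %d players, %s strategies>\n",
              x$label, x$n_players, kind))
  invisible(x)
}

check_profile <- function(s, game) {
  if (length(s) != game$n_players) {
    stop("strategy profile length must equal the number of players",
         call. = FALSE)
  }
  if (!is.null(game$validate_profile)) game$validate_profile(s)
  invisible(s)
}

#' Finite game from payoff tables
#'
#' Builds a [nash_game] from explicit payoff arrays, mainly for small games
#' whose equilibria can be found by exhaustion.  Player `i`'s strategies are
#' `1..dim(payoffs[[i]])[i]`.
#'
#' @param payoffs list with one numeric array per player; array `i` has one
#'   dimension per player and entry `payoffs[[i]][s1, ..., sn]` equal to
#'   \eqn{u_i(s)}.
#' @return a `"nash_game"` with strategy enumeration.
#' @examples
#' # matching pennies
#' u1 <- matrix(c(1, -1, -1, 1), 2)
#' normal_form_game(list(u1, -u1))
#' @export
normal_form_game <- function(payoffs) {
  stopifnot(is.list(payoffs), length(payoffs) >= 2L)
  n <- length(payoffs)
  dims <- dim(payoffs[[1L]])
  if (is.null(dims) || length(dims) != n) {
    stop("each payoff array needs one dimension per player", call. = FALSE)
  }
  for (a in payoffs) {
    if (!identical(dim(a), dims)) {
      stop("all payoff arrays must share the same dimensions", call. = FALSE)
    }
  }
  mult <- cumprod(c(1L, dims[-n]))
  idx <- function(s) sum((s - 1L) * mult) + 1L
  new_nash_game(
    n_players = n,
    payoff = function(i, s) payoffs[[i]][idx(s)],
    deviation_payoff = function(i, qi, s) {
      s[i] <- qi
      payoffs[[i]][idx(s)]
    },
    enumerate_deviations = function(i, s) setdiff(seq_len(dims[i]), s[i]),
    validate_profile = function(s) {
      if (any(s < 1L | s > dims)) {
        stop("strategy outside the game's strategy sets", call. = FALSE)
      }
    },
    label = "normal-form"
  )
}

#' The community structure detection game
#'
#' Wraps a network as a [nash_game]: players are nodes, strategies are
#' community labels, and payoffs are marginal community-fitness
#' contributions ([node_payoff()]).  A player's alternative strategies are
#' every label present in the current profile plus one fresh (empty
#' community) label — any other label is materially identical to the fresh
#' one.
#'
#' @param net a [network()].
#' @param alpha fitness exponent, see [community_fitness()].
#' @return a `"nash_game"` over community label profiles.
#' @examples
#' g <- community_game(demo_network7())
#' g$payoff(3, c(1, 1, 1, 2, 2, 2, 2))  # 5/14
#' @export
community_game <- function(net, alpha = 1) {
  stopifnot(inherits(net, "pmneo_network"))
  force(alpha)
  new_nash_game(
    n_players = net$n,
    payoff = function(i, s) node_payoff(i, s, net, alpha),
    deviation_payoff = function(i, qi, s) deviation_payoff(i, qi, s, net, alpha),
    enumerate_deviations = function(i, s) {
      fresh <- min(setdiff(seq_len(net$n + 1L), s))
      setdiff(c(unique(s), fresh), s[i])
    },
    label = "community detection"
  )
}
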