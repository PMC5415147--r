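#' Nash ascendancy operator k
#'
#' Counts the players that would (weakly) improve by unilaterally switching
#' from profile `s` towards profile `q`:
#' \deqn{k(s, q) = \mathrm{card}\{i \mid u_i(s) \le u_i(q_i, s_{-i}),\;
#'       s_i \ne q_i\}.}
#' Players whose strategies agree in the two profiles are skipped without
#' any payoff evaluation.  The profile with the smaller count is the better
#' one "in Nash sense": `s` Nash ascends `q` when `k(s, q) < k(q, s)`.
#'
#' @param s,q strategy profiles of length `game$n_players`.
#' @param game a [nash_game] object.
#' @param tie `"leq"` counts payoff ties as improvements (the definition the
#'   correctness results rest on, default); `"strict"` requires a strict
#'   payoff increase.
#' @return nonnegative integer count.
#' @examples
#' g <- community_game(demo_network7())
#' s <- c(1, 1, 1, 2, 2, 2, 2); q <- c(1, 1, 2, 2, 2, 2, 1)
#' k_operator(s, q, g)  # 0
#' k_operator(q, s, g)  # 2
#' @export
k_operator <- function(s, q, game, tie = c("leq", "strict")) {
  kp_operator(s, q, seq_len(game$n_players), game, tie = tie)
}

#' Reduced Nash ascendancy operator k_p
#'
#' The same counting rule as [k_operator()], restricted to a subset
#' \eqn{I_p} of the players.  Because only \eqn{[p \cdot n]} players are
#' inspected, comparing two profiles costs at most \eqn{4 [p \cdot n]}
#' payoff evaluations instead of up to \eqn{4n}, while (summed over all
#' subsets of that size) remaining proportional to the full count.
#'
#' @inheritParams k_operator
#' @param subset integer vector of distinct player IDs (\eqn{I_p}), e.g.
#'   from [sample_player_subset()].
#' @return nonnegative integer count over `subset`.
#' @examples
#' g <- community_game(demo_network7())
#' s <- c(1, 1, 1, 2, 2, 2, 2); q <- c(1, 1, 2, 2, 2, 2, 1)
#' kp_operator(s, q, c(1, 3, 5), g)  # 0
#' kp_operator(q, s, c(1, 3, 5), g)  # 1
#' @export
kp_operator <- function(s, q, subset, game, tie = c("leq", "strict")) {
  tie <- match.arg(tie)
  check_profile(s, game)
  check_profile(q, game)
  subset <- as.integer(subset)
  if (length(subset) == 0L || anyDuplicated(subset) ||
      any(subset < 1L | subset > game$n_players)) {
    stop("'subset' must be distinct player IDs in 1..n", call. = FALSE)
  }
  count <- 0L
  for (i in subset) {
    if (s[i] == q[i]) next
    u_now <- game$payoff(i, s)
    u_dev <- game$deviation_payoff(i, q[i], s)
    better <- if (tie == "leq") u_now <= u_dev else u_now < u_dev
    if (better) count <- count + 1L
  }
  count
}

#' Compare two profiles with the p-Nash ascendancy relation
#'
#' Computes `k_p(s, q, I_p)` and `k_p(q, s, I_p)` over the *same* player
#' subset in a single pass and returns the verdict: `s` p-Nash *ascends*
#' `q` when its count is strictly smaller, is *ascended* when strictly
#' larger, and the profiles are *indifferent* on equal counts.  With the
#' full player set this is exactly the Nash ascendancy relation.
#'
#' @inheritParams kp_operator
#' @return an object of class `"nash_ascendancy"`: a list with
#'   `k_forward` (= `k_p(s, q, I_p)`), `k_backward` (= `k_p(q, s, I_p)`)
#'   and `verdict` (`"ascends"`, `"ascended"` or `"indifferent"`).
#' @examples
#' g <- community_game(demo_network7())
#' p_nash_compare(c(1, 1, 1, 2, 2, 2, 2), c(1, 1, 2, 2, 2, 2, 1),
#'                c(1, 3, 5), g)
#' @export
p_nash_compare <- function(s, q, subset, game, tie = c("leq", "strict")) {
  tie <- match.arg(tie)
  kf <- kp_operator(s, q, subset, game, tie = tie)
  kb <- kp_operator(q, s, subset, game, tie = tie)
  verdict <- if (kf < kb) "ascends" else if (kf > kb) "ascended" else "indifferent"
  structure(list(k_forward = kf, k_backward = kb, verdict = verdict),
            class = "nash_ascendancy")
}

#' @export
print.nash_ascendancy <- function(x, ...) {
  cat(sprintf("p-Nash ascendancy: k(s,q) = %d, k(q,s) = %d -> s %s q\n",
              x$k_forward, x$k_backward,
              switch(x$verdict, ascends = "ascends",
                     ascended = "is ascended by",
                     indifferent = "is indifferent to")))
  invisible(x)
}

#' Sample a player subset I_p
#'
#' Draws \eqn{n_p = [p \cdot n]} distinct players uniformly at random
#' ([.] = integer part).  A fresh subset is drawn every time two profiles
#' are compared during the search.  `p` must be large enough that
#' \eqn{n_p \ge 1}.
#'
#' @param n number of players.
#' @param p fraction of players in (0, 1].
#' @param replace sample with replacement instead (the subset may then
#'   contain repeats and is passed around as drawn); kept for comparing the
#'   two possible readings of a per-draw loop, the default set semantics is
#'   what the theory is stated for.
#' @return integer vector of player IDs of length \eqn{[p \cdot n]}.
#' @export
sample_player_subset <- function(n, p, replace = FALSE) {
  n <- as.integer(n)
  np <- floor(p * n)
  if (is.na(np) || np < 1) {
    stop("invalid 'p': n_p = [p * n] must be > 0", call. = FALSE)
  }
  np <- as.integer(min(np, n))
  if (replace) sample.int(n, np, replace = TRUE) else sample.int(n, np)
}

#' Check whether a profile is a Nash equilibrium
#'
#' Exhaustively tests every player's unilateral deviations: player `i` is
#' *improving* when some alternative strategy yields a payoff strictly
#' greater than \eqn{u_i(s)}.  For finite games the alternatives come from
#' `game$enumerate_deviations`; continuous games must supply
#' `game$best_response` (testing the best reply is sufficient).  The
#' fraction of improving players is 0 exactly when `s` is a Nash
#' equilibrium with respect to the tested deviation set.
#'
#' @inheritParams k_operator
#' @param strict require a strictly larger payoff to count a player as
#'   improving (default); `FALSE` counts payoff ties too, for sensitivity
#'   analysis.
#' @return an object of class `"equilibrium_report"`: a list with
#'   `improving_players` (integer IDs) and `fraction` (count / n).
#' @examples
#' g <- community_game(demo_network7())
#' verify_equilibrium(c(1, 1, 1, 2, 2, 2, 2), g)$fraction  # 0
#' @export
verify_equilibrium <- function(s, game, strict = TRUE) {
  check_profile(s, game)
  n <- game$n_players
  improving <- integer(0)
  for (i in seq_len(n)) {
    u_now <- game$payoff(i, s)
    if (!is.null(game$enumerate_deviations)) {
      alts <- game$enumerate_deviations(i, s)
      alts <- alts[alts != s[i]]
      gain <- FALSE
      for (a in alts) {
        u_dev <- game$deviation_payoff(i, a, s)
        if (if (strict) u_dev > u_now else u_dev >= u_now) {
          gain <- TRUE
          break
        }
      }
    } else if (!is.null(game$best_response)) {
      u_dev <- game$deviation_payoff(i, game$best_response(i, s), s)
      gain <- if (strict) u_dev > u_now else u_dev >= u_now
    } else {
      stop("continuous game without a best_response cannot be verified",
           call. = FALSE)
    }
    if (gain) improving <- c(improving, i)
  }
  structure(list(improving_players = improving,
                 fraction = length(improving) / n),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  k <- length(x$improving_players)
  cat(sprintf("Equilibrium check: %d improving player(s), fraction %.4f%s\n",
              k, x$fraction,
              if (k == 0) " (Nash equilibrium)" else ""))
  invisible(x)
}
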