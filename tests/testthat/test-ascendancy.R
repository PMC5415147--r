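demo_profiles <- function() {
  list(s = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
       q = c(1L, 1L, 2L, 2L, 2L, 2L, 1L))
}

test_that("ascendancy counts on the seven-node community game match hand computation", {
  g <- community_game(demo_network7())
  p <- demo_profiles()
  expect_identical(k_operator(p$s, p$q, g), 0L)
  expect_identical(k_operator(p$q, p$s, g), 2L)
  expect_identical(kp_operator(p$s, p$q, c(1, 3, 5), g), 0L)
  expect_identical(kp_operator(p$q, p$s, c(1, 3, 5), g), 1L)
  cmp <- p_nash_compare(p$s, p$q, c(1, 3, 5), g)
  expect_identical(cmp$verdict, "ascends")
  expect_identical(cmp$k_forward, 0L)
  expect_identical(cmp$k_backward, 1L)
})

test_that("identical profiles are skipped entirely and compare as indifferent", {
  # a payoff function that records calls: no player with s_i = q_i may be
  # evaluated
  calls <- new.env()
  calls$n <- 0L
  g <- pmneo:::new_nash_game(
    n_players = 4L,
    payoff = function(i, s) {
      calls$n <- calls$n + 1L
      i + sum(s)
    }
  )
  s <- c(1L, 2L, 1L, 2L)
  expect_identical(k_operator(s, s, g), 0L)
  expect_identical(calls$n, 0L)
  cmp <- p_nash_compare(s, s, 1:4, g)
  expect_identical(cmp$verdict, "indifferent")
  expect_identical(calls$n, 0L)
  # only the one differing player triggers evaluations
  q <- s
  q[2L] <- 1L
  k_operator(s, q, g)
  expect_identical(calls$n, 2L)  # u_2(s) and u_2(q_2, s_-2)
})

test_that("input validation rejects mismatched profiles and bad subsets", {
  g <- community_game(demo_network7())
  p <- demo_profiles()
  expect_error(k_operator(p$s[-1], p$q, g), "length")
  expect_error(kp_operator(p$s, p$q, c(1, 9), g), "subset")
  expect_error(kp_operator(p$s, p$q, c(2, 2), g), "subset")
  expect_error(kp_operator(p$s, p$q, integer(0), g), "subset")
})

test_that("full-subset reduced counts and verdicts agree with an independent oracle", {
  set.seed(41)
  for (rep in 1:50) {
    dims <- sample(2:3, 4, replace = TRUE)
    arrays <- rand_payoff_arrays(4, dims)
    g <- normal_form_game(arrays)
    s <- vapply(dims, function(k) sample.int(k, 1L), integer(1))
    q <- vapply(dims, function(k) sample.int(k, 1L), integer(1))
    expect_identical(kp_operator(s, q, 1:4, g), oracle_k(arrays, s, q))
    expect_identical(k_operator(s, q, g), oracle_k(arrays, s, q))
    cmp <- p_nash_compare(s, q, 1:4, g)
    expect_identical(cmp$verdict, oracle_verdict(arrays, s, q))
  }
})

test_that("subset sums reproduce the full count (binomial identity)", {
  # over all subsets of a fixed size, the reduced counts sum to
  # choose(n-1, np-1) times the full count
  set.seed(17)
  n <- 5L
  for (rep in 1:10) {
    arrays <- rand_payoff_arrays(n, 2L)
    g <- normal_form_game(arrays)
    s <- sample(1:2, n, replace = TRUE)
    q <- sample(1:2, n, replace = TRUE)
    k_full <- k_operator(s, q, g)
    for (np in 1:(n - 1L)) {
      subs <- utils::combn(n, np)
      total <- sum(vapply(seq_len(ncol(subs)), function(c) {
        kp_operator(s, q, subs[, c], g)
      }, integer(1)))
      expect_equal(total, choose(n - 1L, np - 1L) * k_full)
    }
  }
})

test_that("nested subset averages recover the larger-subset count", {
  # for any fixed I_r and np < nr:
  # k_r(s,q,I_r) = sum over I_p subset of I_r of k_p / choose(nr-1, np-1)
  set.seed(18)
  n <- 6L
  arrays <- rand_payoff_arrays(n, 2L)
  g <- normal_form_game(arrays)
  for (rep in 1:5) {
    s <- sample(1:2, n, replace = TRUE)
    q <- sample(1:2, n, replace = TRUE)
    for (nr in 3:5) {
      I_r <- sample.int(n, nr)
      k_r <- kp_operator(s, q, I_r, g)
      for (np in 1:(nr - 1L)) {
        subs <- utils::combn(I_r, np)
        total <- sum(vapply(seq_len(ncol(subs)), function(c) {
          kp_operator(s, q, subs[, c], g)
        }, integer(1)))
        expect_equal(total / choose(nr - 1L, np - 1L), k_r)
      }
    }
  }
})

test_that("Nash equilibria are never ascended under any subset, and the reduced non-ascended set is contained in the full one", {
  set.seed(23)
  found_ne <- 0L
  for (rep in 1:12) {
    dims <- sample(2:3, 3, replace = TRUE)
    arrays <- rand_payoff_arrays(3, dims)
    g <- normal_form_game(arrays)
    ne <- oracle_ne_set(arrays, dims)
    found_ne <- found_ne + nrow(ne)
    profs <- all_profiles(dims)
    subsets <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
    for (r in seq_len(nrow(ne))) {
      s <- ne[r, ]
      # the equilibrium checker agrees it is an equilibrium
      expect_identical(verify_equilibrium(s, g)$fraction, 0)
      # and no rival profile ascends it under any subset
      for (rr in seq_len(nrow(profs))) {
        q <- profs[rr, ]
        for (sub in subsets) {
          expect_false(
            kp_operator(q, s, sub, g) < kp_operator(s, q, sub, g)
          )
        }
      }
    }
    pnnd <- oracle_pnnd_set(arrays, dims)
    nnd <- oracle_nnd_set(arrays, dims)
    key <- function(m) apply(m, 1L, paste, collapse = "-")
    expect_true(all(key(pnnd) %in% key(nnd)))
    # when equilibria exist they sit inside the reduced non-ascended set
    if (nrow(ne)) expect_true(all(key(ne) %in% key(pnnd)))
  }
  expect_gt(found_ne, 0L)  # the sweep did exercise games with equilibria
})

test_that("comparison verdicts are antisymmetric", {
  set.seed(7)
  g <- community_game(demo_network7())
  for (rep in 1:25) {
    s <- sample.int(3, 7, replace = TRUE)
    q <- sample.int(3, 7, replace = TRUE)
    sub <- sample.int(7, sample.int(7, 1))
    a <- p_nash_compare(s, q, sub, g)$verdict
    b <- p_nash_compare(q, s, sub, g)$verdict
    expect_identical(
      a,
      switch(b, ascends = "ascended", ascended = "ascends",
             indifferent = "indifferent")
    )
  }
})

test_that("tie handling switches between weak and strict improvement counting", {
  # player 1 is exactly indifferent between its two strategies
  u1 <- matrix(c(1, 1, 0, 0), nrow = 2)   # u1 constant in own strategy
  u2 <- matrix(c(0, 0, 1, 2), nrow = 2)
  g <- normal_form_game(list(u1, u2))
  s <- c(1L, 1L)
  q <- c(2L, 1L)
  expect_identical(k_operator(s, q, g, tie = "leq"), 1L)
  expect_identical(k_operator(s, q, g, tie = "strict"), 0L)
})

test_that("player subsets have size [p * n] and respect the sampling mode", {
  set.seed(5)
  expect_length(sample_player_subset(7, 0.5), 3L)
  expect_setequal(sample_player_subset(10, 1.0), 1:10)
  expect_length(sample_player_subset(10, 0.25), 2L)
  expect_error(sample_player_subset(10, 0.05), "n_p = \\[p \\* n\\] must be > 0")
  for (rep in 1:20) {
    sub <- sample_player_subset(9, 0.7)
    expect_identical(anyDuplicated(sub), 0L)
    expect_true(all(sub >= 1 & sub <= 9))
  }
  # with replacement, repeats are possible (and expected eventually)
  reps <- replicate(50, anyDuplicated(sample_player_subset(5, 1, replace = TRUE)))
  expect_true(any(reps > 0))
})

test_that("equilibrium verification flags exactly the improving players", {
  # build a 2x2 game where player 2 strictly gains by deviating from (1,1)
  u1 <- matrix(c(5, 0, 0, 0), nrow = 2)
  u2 <- matrix(c(0, 0, 3, 1), nrow = 2)  # u2(1,1)=0 < u2(1,2)=3
  g <- normal_form_game(list(u1, u2))
  rep <- verify_equilibrium(c(1L, 1L), g)
  expect_identical(rep$improving_players, 2L)
  expect_equal(rep$fraction, 0.5)
  # continuous game without a best response cannot be verified
  g_cont <- pmneo:::new_nash_game(2L, payoff = function(i, s) -sum(s^2))
  expect_error(verify_equilibrium(c(0, 0), g_cont), "best_response")
})
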