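test_that("the mutation-size schedule decays linearly to one", {
  expect_identical(ell_schedule(128, 0, 500), 13L)
  expect_identical(ell_schedule(128, 500, 500), 1L)
  vals <- vapply(0:500, function(g) ell_schedule(128, g, 500), integer(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 1))
})

test_that("population initialization honours sizes, budgets and pinning", {
  set.seed(71)
  net <- generate_gn(2)$network
  params <- eo_params(pop_size = 48, c_min = 5, c_max = 8,
                      pinned_fraction = 0.25, pinned_count = 5)
  # pin a count outside the random range to count the pinned individuals
  params$pinned_count <- 4L
  params$c_min <- 4L
  st <- initialize_populations(net, params)
  expect_length(st$pop, 48L)
  expect_length(st$arch, 48L)
  budgets <- vapply(st$pop, `[[`, integer(1), "budget")
  expect_identical(budgets[1:12], rep(4L, 12))
  for (ind in c(st$pop, st$arch)) {
    expect_true(all(ind$lab >= 1L & ind$lab <= ind$budget))
  }
  expect_error(eo_params(c_min = 5, c_max = 3), "c_max")
  expect_error(
    initialize_populations(network(rbind(c(1, 2), c(2, 3))),
                           eo_params(p = 0.1, c_max = 2)),
    "n_p = \\[p \\* n\\] must be > 0"
  )
})

test_that("one EO generation mutates at most ell nodes and always replaces the parent", {
  set.seed(72)
  net <- generate_gn(2)$network
  params <- eo_params(pop_size = 10, c_min = 3, c_max = 6, p = 0.5)
  st <- initialize_populations(net, params)
  for (ell in c(1L, 5L)) {
    before <- lapply(st$pop, `[[`, "lab")
    arch_before <- lapply(st$arch, `[[`, "lab")
    st <- eo_iteration(st, ell = ell)
    for (j in seq_along(st$pop)) {
      changed <- sum(st$pop[[j]]$lab != before[[j]])
      expect_lte(changed, ell)
      expect_gt(changed, 0L)  # the population member is its offspring
      # the archive is either untouched or replaced by the offspring
      expect_true(identical(st$arch[[j]]$lab, arch_before[[j]]) ||
                    identical(st$arch[[j]]$lab, st$pop[[j]]$lab))
    }
  }
  expect_identical(st$generation, 2L)
})

test_that("incremental aggregates stay consistent through a run", {
  set.seed(73)
  net <- rand_network(20, 0.25)
  params <- eo_params(pop_size = 5, c_min = 2, c_max = 4, p = 0.5)
  st <- initialize_populations(net, params)
  for (g in 1:10) st <- eo_iteration(st, ell = 2L)
  for (ind in c(st$pop, st$arch)) {
    fresh <- pmneo:::.agg(ind$lab, ind$budget, net)
    expect_equal(ind$L, fresh$L, tolerance = 1e-12)
    expect_equal(ind$D, fresh$D, tolerance = 1e-12)
    expect_equal(ind$u, pmneo:::.payoffs_all(ind$lab, fresh$L, fresh$D,
                                             net, 1),
                 tolerance = 1e-12)
  }
})

test_that("network mixing preserves degrees and simplicity, and is inert where it must be", {
  set.seed(74)
  net <- generate_gn(4)$network
  expect_identical(mix_network(net, 0)$edges, net$edges)
  for (rho in c(0.02, 0.2, 1)) {
    mixed <- mix_network(net, rho)
    expect_identical(mixed$deg, net$deg)
    expect_identical(mixed$m, net$m)
    expect_identical(anyDuplicated(paste(mixed$edges[, 1], mixed$edges[, 2])),
                     0L)
    expect_true(all(mixed$edges[, 1] != mixed$edges[, 2]))
  }
  # on a complete graph every rewiring creates a duplicate: nothing can move
  k4 <- network(t(utils::combn(4, 2)))
  expect_identical(mix_network(k4, 1)$edges, k4$edges)
})

test_that("phase bookkeeping alternates the designed spans of original and mixed search", {
  set.seed(75)
  net <- rand_network(16, 0.3)
  fit <- pmneo(net, c_min = 2, c_max = 4, p = 0.5, max_gen = 27,
               pop_size = 4, lambda_big = 6, lambda_small = 3)
  phases <- fit$diagnostics$phase
  expected <- rep(rep(c("original", "mixed"), times = c(6, 3)), length.out = 27)
  expect_identical(phases, expected)
  # every window of lambda_big + lambda_small has exactly lambda_small mixed
  for (start in 1:(27 - 9 + 1)) {
    expect_identical(sum(phases[start:(start + 8)] == "mixed"), 3L)
  }
})

test_that("runs are reproducible and respect the community budget", {
  net <- demo_network7()
  f1 <- pmneo(net, c_min = 2, c_max = 3, p = 0.5, max_gen = 40,
              pop_size = 8, seed = 99)
  f2 <- pmneo(net, c_min = 2, c_max = 3, p = 0.5, max_gen = 40,
              pop_size = 8, seed = 99)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$eval_count, f2$eval_count)
  expect_lte(length(unique(f1$membership)), 3L)
  # reported partition is the best-modularity archive member, so its Q is
  # attainable by definition
  expect_equal(f1$modularity, modularity_q(f1$membership, net),
               tolerance = 1e-12)
})

test_that("two cliques joined by one edge are recovered in nearly every run", {
  # brute-force oracle: over all 2-colourings of the 10 nodes, the split
  # into the two 5-cliques maximizes modularity
  clique <- t(utils::combn(5, 2))
  edges <- rbind(clique, clique + 5L, c(5L, 6L))
  net <- network(edges)
  truth <- rep(1:2, each = 5)
  best_q <- -Inf
  best_split <- NULL
  for (code in 0:(2^9 - 1)) {  # node 1 fixed in community 1
    lab <- c(1L, as.integer(intToBits(code))[1:9] + 1L)
    q <- modularity_q(lab, net)
    if (q > best_q) {
      best_q <- q
      best_split <- lab
    }
  }
  expect_equal(nmi(best_split, truth), 1, tolerance = 1e-12)
  hits <- 0L
  for (s in 1:10) {
    fit <- pmneo(net, c_min = 2, c_max = 3, p = 0.5, max_gen = 80,
                 pop_size = 20, seed = 500 + s, trace = FALSE)
    if (isTRUE(all.equal(nmi(fit$membership, truth), 1))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("reducing p reduces the payoff evaluations logged in comparisons", {
  set.seed(76)
  net <- generate_gn(3)$network
  f_small <- pmneo(net, c_min = 2, c_max = 8, p = 0.25, max_gen = 40,
                   pop_size = 10, pinned_count = 4, seed = 3, trace = FALSE)
  f_full <- pmneo(net, c_min = 2, c_max = 8, p = 1, max_gen = 40,
                  pop_size = 10, pinned_count = 4, seed = 3, trace = FALSE)
  expect_lt(f_small$eval_count, f_full$eval_count)
})

test_that("run reports serialize the run and its diagnostics", {
  net <- demo_network7()
  fit <- pmneo(net, c_min = 2, c_max = 3, p = 0.5, max_gen = 20,
               pop_size = 6, seed = 4)
  f <- withr::local_tempfile()
  write_run_report(fit, f, truth = c(1, 1, 1, 2, 2, 2, 2))
  lines <- readLines(f)
  expect_true(any(grepl("^seed 4$", lines)))
  expect_true(any(grepl("^modularity ", lines)))
  expect_true(any(grepl("^nmi ", lines)))
  expect_true(any(grepl("^generation\tbest_q", lines)))
})
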