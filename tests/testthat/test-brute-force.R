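test_that("a single shared hyperedge is decided by the first parent", {
  H <- hypergraph(list(c(1, 2, 3)))
  for (r in c(0.5, 1, 2, 4)) {
    expect_equal(brute_force_fixation(H, 1, r, i = 1)$probability,
                 r / (r + 2), tolerance = 1e-12)
  }
})

test_that("brute force matches the reduced chains on all families and models", {
  for (N in 4:8) {
    for (r in c(0.5, 1, 2)) {
      for (fam in c("complete3", "cyclic3", "star3")) {
        H <- make_model_hypergraph(fam, N)
        for (model in 1:2) {
          if (fam == "cyclic3" && model == 2) {
            ex <- closed_form_fixation(fam, 2, N, r, 2)
            bf <- brute_force_fixation(H, 2, r, i = 2)$probability
          } else {
            i <- if (model == 1) 1 else 2
            sol <- solve_absorption(build_reduced_chain(fam, model, N, r))
            ex <- fixation_from_solution(sol, i)
            bf <- brute_force_fixation(H, model, r, i = i)$probability
          }
          expect_equal(bf, ex, tolerance = 1e-10,
                       label = sprintf("%s m%d N%d r%.1f brute", fam, model, N, r),
                       expected.label = "exact")
        }
      }
    }
  }
})

test_that("neutral drift fixes at i/N on arbitrary connected hypergraphs", {
  set.seed(20)
  for (rep in 1:8) {
    N <- sample(5:9, 1)
    H <- random_hypergraph(N, N + sample(2:5, 1), sizes = 2:4,
                           seed = 100 + rep)
    i <- sample(seq_len(N - 1), 1)
    expect_equal(brute_force_fixation(H, 1, 1, i = i)$probability, i / N,
                 tolerance = 1e-10)
  }
})

test_that("model 2 on the printed 6-node example never fixates from {1, 2}", {
  H <- hypergraph(list(c(1, 2, 3), c(3, 4, 5), c(4, 5, 6), c(6, 1, 2)))
  for (r in c(0.5, 1, 2)) {
    bf <- brute_force_fixation(H, 2, r, mutants = c(1, 2))
    expect_equal(bf$probability, 0)
    expect_equal(bf$prob_resident, 0)
    expect_equal(bf$never_fix, 1)
  }
  # under model 1 the same start fixates almost surely
  bf1 <- brute_force_fixation(H, 1, 1, mutants = c(1, 2))
  expect_equal(bf1$probability + bf1$prob_resident, 1, tolerance = 1e-12)
})

test_that("model-2 boundary identities hold on the 3-uniform families", {
  for (fam in c("complete3", "cyclic3", "star3")) {
    H <- make_model_hypergraph(fam, 6)
    bf_lo <- brute_force_fixation(H, 2, 1.5, i = 1)
    bf_hi <- brute_force_fixation(H, 2, 1.5, i = 5)
    expect_equal(bf_lo$probability, 0)
    expect_equal(bf_hi$probability, 1)
  }
})

test_that("the guard rails reject infeasible calls", {
  H <- make_model_hypergraph("complete3", 5)
  expect_error(brute_force_fixation(H, 1, -2, i = 1), "positive")
  expect_error(brute_force_fixation(H, 1, 1), "exactly one")
  expect_error(brute_force_fixation(H, 1, 1, i = 1, mutants = 2), "exactly one")
  big <- make_model_hypergraph("cyclic3", 15)
  expect_error(brute_force_fixation(big, 1, 1, i = 1), "N <= 14")
  expect_error(
    brute_force_fixation(hypergraph(list(c(1, 2), c(3, 4)), n_nodes = 4),
                         1, 1, i = 1),
    "connected"
  )
})
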