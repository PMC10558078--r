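test_that("single steps follow the conversion rules", {
  # model 1: the parent's hyperedge becomes unanimous for the parent type
  H <- hypergraph(list(c(1, 2, 3)))
  set.seed(4)
  s <- sim_step(H, c(1, 0, 0), 1, 1e6) # mutant parent almost surely
  expect_equal(s, c(1L, 1L, 1L))
  # model 2 tie on an even hyperedge changes nothing
  H4 <- hypergraph(list(c(1, 2, 3, 4)))
  for (seed in 1:5) {
    set.seed(seed)
    expect_equal(sim_step(H4, c(1, 1, 0, 0), 2, 1), c(1L, 1L, 0L, 0L))
  }
  # model 2 minority parent changes nothing
  H3 <- hypergraph(list(c(1, 2, 3)))
  set.seed(1)
  expect_equal(sim_step(H3, c(1, 0, 0), 2, 1e6), c(1L, 0L, 0L))
})

test_that("absorbing states are never left", {
  H <- make_model_hypergraph("cyclic3", 6)
  out <- run_to_fixation(H, 1, 2, init = rep(1L, 6), seed = 1)
  expect_equal(out$result, "mutant_fixed")
  expect_equal(out$steps, 0)
  out <- run_to_fixation(H, 2, 2, init = rep(0L, 6), seed = 1)
  expect_equal(out$result, "resident_fixed")
  expect_equal(out$steps, 0)
})

test_that("the toggling 6-node start always times out under model 2", {
  H <- hypergraph(list(c(1, 2, 3), c(3, 4, 5), c(4, 5, 6), c(6, 1, 2)))
  for (seed in 1:5) {
    out <- run_to_fixation(H, 2, 1, init = c(1, 2), seed = seed,
                           max_steps = 3000)
    expect_equal(out$result, "timeout")
  }
})

test_that("one-step transition frequencies match the reduced-chain row", {
  # complete family, N = 6, 3 mutants, r = 2: compare empirical jump
  # frequencies over many single steps with the pentadiagonal row p_{3,.}
  N <- 6; r <- 2; n_steps <- 4e4
  H <- make_model_hypergraph("complete3", N)
  ch <- build_reduced_chain("complete3", 1, N, r)
  p_row <- as.numeric(ch$P[4, ]) # state i = 3
  set.seed(99)
  state0 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  counts <- integer(N + 1)
  for (k in seq_len(n_steps)) {
    s <- sim_step(H, sample(state0), 1, r) # random relabeling, same i
    j <- sum(s)
    counts[j + 1] <- counts[j + 1] + 1L
  }
  for (j in 1:6) {
    p <- p_row[j]
    if (p == 0) {
      expect_equal(counts[j], 0L)
    } else {
      se <- sqrt(p * (1 - p) / n_steps)
      expect_lt(abs(counts[j] / n_steps - p), 3.5 * se + 1e-12)
    }
  }
})

test_that("estimates agree with exact values within 3 standard errors", {
  cases <- expand.grid(fam = c("complete3", "cyclic3", "star3"),
                       model = 1:2, r = c(0.5, 2),
                       stringsAsFactors = FALSE)
  N <- 5
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    i <- if (cs$model == 1) 1 else 2
    H <- make_model_hypergraph(cs$fam, N)
    if (cs$fam == "cyclic3" && cs$model == 2) {
      ex <- closed_form_fixation(cs$fam, 2, N, cs$r, 2)
    } else {
      ex <- fixation_from_solution(
        solve_absorption(build_reduced_chain(cs$fam, cs$model, N, cs$r)), i)
    }
    est <- estimate_fixation(H, cs$model, cs$r, i = i, runs_per_start = 800,
                             seed = 300 + k)
    n_eff <- est$runs - est$timeouts
    se <- sqrt(max(ex * (1 - ex), 1e-12) / n_eff)
    expect_lt(abs(est$estimate - ex), 3 * se + 1e-9,
              label = sprintf("%s m%d r%.1f estimate", cs$fam, cs$model, cs$r))
  }
})

test_that("estimation is deterministic in the root seed and CI covers it", {
  H <- make_model_hypergraph("complete3", 5)
  a <- estimate_fixation(H, 1, 2, i = 1, runs_per_start = 500, seed = 11)
  b <- estimate_fixation(H, 1, 2, i = 1, runs_per_start = 500, seed = 11)
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$fixations, b$fixations)
  expect_true(a$ci_low <= a$estimate && a$estimate <= a$ci_high)
  # i >= 2 path, enumerated and sampled starts both reproducible
  c1 <- estimate_fixation(H, 2, 1.5, i = 2, runs_per_start = 200, seed = 5,
                          enumerate = TRUE)
  c2 <- estimate_fixation(H, 2, 1.5, i = 2, runs_per_start = 200, seed = 5,
                          enumerate = TRUE)
  expect_identical(c1$estimate, c2$estimate)
})
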