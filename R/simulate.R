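#' One update step of the evolutionary dynamics
#'
#' Draws a parent proportional to fitness (`r` for mutants, 1 for residents),
#' draws one of the parent's incident hyperedges uniformly (duplicates in the
#' multiset counted), and applies the conversion rule: model 1 converts all
#' co-members unconditionally; model 2 converts only when the parent's type
#' is held by strictly more than half of the hyperedge members (parent
#' included), so ties and minority parents change nothing. Uses R's RNG
#' stream, so results are reproducible under [set.seed()].
#'
#' @param H a connected `hypergraph`.
#' @param state logical or 0/1 integer vector of length `N`; `TRUE`/1 marks a
#'   mutant.
#' @param model 1 or 2.
#' @param r relative fitness (`> 0`).
#' @return the updated 0/1 state vector.
#' @export
sim_step <- function(H, state, model, r) {
  stopifnot(inherits(H, "hypergraph"), model %in% c(1, 2), r > 0)
  state <- as.integer(state)
  stopifnot(length(state) == H$n, all(state %in% c(0L, 1L)))
  parts <- sim_parts(H)
  .sim_step_cpp(parts$edges, parts$incid, state, as.integer(model), r)
}

# 0-based hyperedge and incidence lists for the compiled core
sim_parts <- function(H) {
  prof <- degree_size_profile(H)
  if (any(prof$degrees == 0L)) stop("every node must belong to a hyperedge")
  list(
    edges = lapply(H$hyperedges, function(e) e - 1L),
    incid = lapply(incidence_list(H), function(k) k - 1L)
  )
}

#' Run the dynamics to fixation
#'
#' Iterates [sim_step()] until the population is unanimous or `max_steps` is
#' reached. Model 1 fixates with probability one on a connected hypergraph;
#' model 2 can cycle forever, so a finite cap with an explicit `timeout`
#' outcome is essential there.
#'
#' @inheritParams sim_step
#' @param init logical or 0/1 vector of length `N`, or an integer vector of
#'   mutant node indices (interpreted as such when shorter than `N`).
#' @param seed optional integer seed.
#' @param max_steps step cap; defaults to `1e4 * N` for model 1 and
#'   `1e3 * N^2` for model 2.
#' @return a list of class `sim_outcome`: `result` (`"mutant_fixed"`,
#'   `"resident_fixed"` or `"timeout"`), `steps`, and the final `state`.
#' @examples
#' H <- make_model_hypergraph("complete3", 5)
#' run_to_fixation(H, 1, 2, init = c(1, 3), seed = 1)
#' @export
run_to_fixation <- function(H, model, r, init, seed = NULL, max_steps = NULL) {
  stopifnot(inherits(H, "hypergraph"), model %in% c(1, 2), r > 0)
  state <- init_state(H$n, init)
  if (is.null(max_steps)) {
    max_steps <- if (model == 1) 1e4 * H$n else 1e3 * H$n^2
  }
  if (!is.null(seed)) set.seed(seed)
  parts <- sim_parts(H)
  out <- .sim_runs_cpp(parts$edges, parts$incid,
                       matrix(state, nrow = 1), 1L,
                       as.integer(model), r, as.numeric(max_steps))
  structure(
    list(result = c("timeout", "resident_fixed", "mutant_fixed")[out$result[1] + 2L],
         steps = out$steps[1],
         state = state),
    class = "sim_outcome"
  )
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("<sim_outcome> ", x$result, " after ", format(x$steps, big.mark = ","),
      " steps\n", sep = "")
  invisible(x)
}

init_state <- function(N, init) {
  init <- as.integer(init)
  if (length(init) == N && all(init %in% c(0L, 1L))) return(init)
  if (any(init < 1L | init > N) || anyDuplicated(init)) {
    stop("init must be a 0/1 vector of length N or distinct node indices")
  }
  state <- integer(N)
  state[init] <- 1L
  state
}

#' Estimate the fixation probability by stochastic simulation
#'
#' Implements the uniform-initialization protocol: for `i = 1` every node is
#' used as the initial mutant in turn, with `runs_per_start` independent runs
#' per start; for `i >= 2` each run draws a uniform random set of `i` mutant
#' nodes (exhaustive enumeration of all `choose(N, i)` starts is available via
#' `enumerate = TRUE` for small `N`). The estimate is the fraction of runs in
#' which the mutant fixated. Under model 2 runs can time out (the dynamics
#' admits non-absorbing cycles); timeouts are reported separately and
#' excluded from the denominator. Under model 1 a timeout would be a budget
#' artifact, so it is counted in the denominator as non-fixation and flagged
#' in the result.
#'
#' Per-start seeds are derived deterministically from `seed`, so a repeated
#' call reproduces the estimate exactly.
#'
#' @inheritParams sim_step
#' @param i initial mutant count, `1 <= i <= N - 1`.
#' @param runs_per_start independent runs per start (for `i = 1`, per node;
#'   otherwise total runs = `runs_per_start * N` to mirror the per-node
#'   budget).
#' @param seed integer root seed.
#' @param max_steps step cap per run; see [run_to_fixation()] defaults.
#' @param enumerate if `TRUE` and `i >= 2`, cycle deterministically through
#'   all `choose(N, i)` mutant sets instead of sampling them.
#' @return a one-row tibble of class `fixation_estimate`: `r`, `i`,
#'   `estimate`, Wilson 95% bounds `ci_low`/`ci_high`, `runs`, `fixations`,
#'   `timeouts`, `mean_steps`.
#' @examples
#' H <- make_model_hypergraph("complete3", 5)
#' estimate_fixation(H, 1, 1, i = 1, runs_per_start = 200, seed = 1)
#' @export
estimate_fixation <- function(H, model, r, i, runs_per_start = 3e3, seed = 1,
                              max_steps = NULL, enumerate = FALSE) {
  stopifnot(inherits(H, "hypergraph"), model %in% c(1, 2), r > 0)
  N <- H$n
  if (i < 1 || i > N - 1) stop("i must be between 1 and N - 1")
  if (is.null(max_steps)) {
    max_steps <- if (model == 1) 1e4 * N else 1e3 * N^2
  }
  parts <- sim_parts(H)
  runs_per_start <- as.integer(runs_per_start)

  n_fix <- 0L; n_timeout <- 0L; n_runs <- 0L; tot_steps <- 0
  run_batch <- function(inits, n_runs_batch, batch_seed) {
    set.seed(batch_seed)
    out <- .sim_runs_cpp(parts$edges, parts$incid, inits, n_runs_batch,
                         as.integer(model), r, as.numeric(max_steps))
    n_fix <<- n_fix + sum(out$result == 1L)
    n_timeout <<- n_timeout + sum(out$result == -1L)
    n_runs <<- n_runs + n_runs_batch
    tot_steps <<- tot_steps + sum(out$steps)
  }

  if (i == 1) {
    for (v in seq_len(N)) {
      state <- integer(N); state[v] <- 1L
      run_batch(matrix(state, nrow = 1), runs_per_start,
                derive_seed(seed, v))
    }
  } else {
    total <- runs_per_start * N
    set.seed(derive_seed(seed, 0L))
    if (enumerate) {
      sets <- utils::combn(N, i, simplify = FALSE)
      idx <- rep_len(seq_along(sets), total)
    } else {
      sets <- replicate(total, sample.int(N, i), simplify = FALSE)
      idx <- seq_len(total)
    }
    inits <- matrix(0L, nrow = total, ncol = N)
    for (run in seq_len(total)) inits[run, sets[[idx[run]]]] <- 1L
    run_batch(inits, total, derive_seed(seed, 1L))
  }

  denom <- if (model == 2) n_runs - n_timeout else n_runs
  est <- if (denom > 0) n_fix / denom else NA_real_
  ci <- wilson_ci(n_fix, denom)
  out <- tibble::tibble(
    r = r, i = i, estimate = est,
    ci_low = ci[1], ci_high = ci[2],
    runs = n_runs, fixations = n_fix, timeouts = n_timeout,
    mean_steps = tot_steps / n_runs
  )
  class(out) <- c("fixation_estimate", class(out))
  attr(out, "model") <- model
  attr(out, "N") <- N
  out
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 104729 * as.numeric(k)) %%
               2147483647) + 1L
}

# Wilson score interval at 95%; well-behaved for estimates near 0 and 1.
wilson_ci <- function(successes, n, z = 1.959964) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- successes / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
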