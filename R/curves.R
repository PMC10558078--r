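#' Fixation probability as a function of fitness
#'
#' Sweeps the fixation probability of `i` uniformly placed mutants over a
#' fitness grid, dispatching per point to the cheapest exact route available:
#' the printed closed form where covered, otherwise the symmetry-reduced
#' linear solve, otherwise the brute-force kernel (for arbitrary hypergraphs
#' with `N <= 14`), or stochastic simulation on request.
#'
#' @param target a family name (`"complete3"`, `"cyclic3"`, `"star3"`) or a
#'   `hypergraph` object.
#' @param model 1 or 2.
#' @param i initial mutant count.
#' @param r_values fitness grid (all `> 0`); defaults to
#'   [default_r_grid()].
#' @param N node count; required when `target` is a family name.
#' @param method `"auto"` (closed form, then reduced solve, then brute
#'   force), or one of `"closed_form"`, `"exact"` (reduced solve),
#'   `"brute_force"`, `"simulation"`.
#' @param runs_per_start,seed,max_steps simulation controls, see
#'   [estimate_fixation()].
#' @return a tibble of class `fixation_curve` with columns `r`, `x`,
#'   `method`, and for simulated points `ci_low`/`ci_high` and `se`;
#'   attributes `N`, `i`, `model` and a target description.
#' @examples
#' fixation_curve("complete3", 1, i = 1, N = 4, r_values = c(0.5, 1, 2))
#' @export
fixation_curve <- function(target, model, i, r_values = default_r_grid(),
                           N = NULL, method = c("auto", "closed_form", "exact",
                                                "brute_force", "simulation"),
                           runs_per_start = 3e3, seed = 1, max_steps = NULL) {
  method <- match.arg(method)
  stopifnot(all(r_values > 0), model %in% c(1, 2))
  is_family <- is.character(target)
  if (is_family) {
    family <- match.arg(target, c("complete3", "cyclic3", "star3"))
    if (is.null(N)) stop("N is required when target is a family name")
    N <- as.integer(N)
    H <- NULL
  } else {
    stopifnot(inherits(target, "hypergraph"))
    H <- target
    N <- H$n
    family <- NULL
  }
  if (i < 1 || i > N - 1) stop("i must be between 1 and N - 1")
  if (method == "simulation" && is.null(H)) H <- make_model_hypergraph(family, N)

  one_point <- function(r) {
    if (method == "simulation") {
      est <- estimate_fixation(H, model, r, i, runs_per_start, seed,
                               max_steps = max_steps)
      p <- est$estimate
      n_eff <- est$runs - est$timeouts
      return(tibble::tibble(r = r, x = p, method = "simulation",
                            ci_low = est$ci_low, ci_high = est$ci_high,
                            se = sqrt(p * (1 - p) / n_eff)))
    }
    if (!is_family) {
      if (method %in% c("closed_form", "exact")) {
        stop("methods 'closed_form' and 'exact' need a symmetric family; ",
             "for an arbitrary hypergraph use 'brute_force' (N <= 14) or ",
             "'simulation'")
      }
      x <- brute_force_fixation(H, model, r, i = i)$probability
      return(tibble::tibble(r = r, x = x, method = "brute_force"))
    }
    if (method %in% c("auto", "closed_form")) {
      x <- tryCatch(closed_form_fixation(family, model, N, r, i),
                    error = function(e) NULL)
      if (!is.null(x)) return(tibble::tibble(r = r, x = x, method = "closed_form"))
      if (method == "closed_form") {
        stop("no printed closed form covers (", family, ", model ", model,
             ", N = ", N, ", i = ", i, ")")
      }
    }
    ch <- tryCatch(build_reduced_chain(family, model, N, r),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      x <- fixation_from_solution(solve_absorption(ch), i)
      return(tibble::tibble(r = r, x = x, method = "reduced_exact"))
    }
    if (method == "exact") {
      stop("no reduced chain for (", family, ", model ", model, ")")
    }
    x <- brute_force_fixation(make_model_hypergraph(family, N), model, r,
                              i = i)$probability
    tibble::tibble(r = r, x = x, method = "brute_force")
  }

  out <- dplyr::bind_rows(lapply(r_values, one_point))
  new_fixation_curve(out, N = N, i = i, model = model,
                     target = if (is_family) family else format(H))
}

new_fixation_curve <- function(tbl, N, i, model, target) {
  class(tbl) <- c("fixation_curve", class(tbl))
  attr(tbl, "N") <- N
  attr(tbl, "i") <- i
  attr(tbl, "model") <- model
  attr(tbl, "target") <- target
  tbl
}

#' Moran baseline curve
#'
#' @param N population size.
#' @param i initial mutant count.
#' @param r_values fitness grid.
#' @return a `fixation_curve` tibble for the Moran process.
#' @export
moran_curve <- function(N, i, r_values = default_r_grid()) {
  tbl <- tibble::tibble(r = r_values, x = moran_fixation(N, r_values, i),
                        method = "closed_form")
  new_fixation_curve(tbl, N = N, i = i, model = 1, target = "moran")
}

#' Default fitness grid
#'
#' 25 log-spaced points on `[1/4, 4]` with `r = 1` included exactly, so both
#' selection regimes are sampled symmetrically in `log r` and the neutral
#' anchor is always present.
#'
#' @param n_points grid size (including the anchor).
#' @param range lower and upper fitness bounds.
#' @return increasing numeric vector of fitness values.
#' @export
default_r_grid <- function(n_points = 25, range = c(0.25, 4)) {
  g <- exp(seq(log(range[1]), log(range[2]), length.out = n_points))
  sort(unique(c(g, 1)))
}

#' Convert a simulation sweep to a fixation curve
#'
#' @param H hypergraph.
#' @param model,i,r_values,runs_per_start,seed,max_steps see
#'   [estimate_fixation()].
#' @return a `fixation_curve` with simulation uncertainty columns.
#' @export
simulate_curve <- function(H, model, i, r_values = default_r_grid(),
                           runs_per_start = 3e3, seed = 1, max_steps = NULL) {
  fixation_curve(H, model, i, r_values, method = "simulation",
                 runs_per_start = runs_per_start, seed = seed,
                 max_steps = max_steps)
}

#' Glance at a fixation curve
#'
#' @param x a `fixation_curve`.
#' @param ... unused.
#' @return a one-row tibble: target, model, `N`, `i`, grid size, the value at
#'   `r = 1` (if present) and the Moran-baseline value there.
#' @importFrom generics glance
#' @export
glance.fixation_curve <- function(x, ...) {
  N <- attr(x, "N"); i <- attr(x, "i")
  at1 <- x$x[abs(x$r - 1) < 1e-12]
  tibble::tibble(
    target = attr(x, "target"), model = attr(x, "model"), N = N, i = i,
    n_points = nrow(x),
    x_at_r1 = if (length(at1)) at1[1] else NA_real_,
    moran_at_r1 = i / N
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
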