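#' Symmetry-reduced transition matrix for a model hypergraph family
#'
#' For the three symmetric 3-uniform families the full 2^N-state chain
#' collapses onto a small state space: the mutant count `i` in `0:N` for the
#' complete and cyclic families, and the pair (hub type, mutant leaf count)
#' for the star family. The resulting transition matrices are pentadiagonal
#' (complete, model 1; cyclic, model 1), tridiagonal (complete, model 2) or
#' general sparse 2N x 2N (star, both models).
#'
#' For the cyclic family under model 1 the reduction is valid only when the
#' mutants form a single consecutive block (in particular for a single
#' initial mutant), because the dynamics preserves that property. The cyclic
#' family under model 2 has no exposed reduced chain; use
#' [closed_form_fixation()] for it.
#'
#' @param family `"complete3"`, `"cyclic3"` or `"star3"`.
#' @param model `1` (unconditional conversion) or `2` (strict-majority rule).
#' @param N node count (family minimum applies, see
#'   [make_model_hypergraph()]).
#' @param r relative fitness of the mutant type (`> 0`).
#' @return an object of class `reduced_chain`: fields `family`, `model`, `N`,
#'   `r`, `P` (sparse row-stochastic `dgCMatrix`), `states` (data frame
#'   describing each reduced state), `absorbing` (state indices), and
#'   `fixation_state` (index of the all-mutant state).
#' @examples
#' ch <- build_reduced_chain("complete3", 1, 6, 2)
#' range(Matrix::rowSums(ch$P)) # rows sum to one
#' @export
build_reduced_chain <- function(family = c("complete3", "cyclic3", "star3"),
                                model, N, r) {
  family <- match.arg(family)
  stopifnot(model %in% c(1, 2), r > 0)
  N <- as.integer(N)
  if (family == "cyclic3" && model == 2) {
    stop("no reduced chain for (cyclic3, model 2); supported pairs are ",
         "(complete3, 1|2), (cyclic3, 1), (star3, 1|2). ",
         "Use closed_form_fixation() for cyclic3 under model 2.")
  }
  min_n <- c(complete3 = 3L, cyclic3 = 4L, star3 = 4L)[[family]]
  if (N < min_n) stop("family '", family, "' requires N >= ", min_n)

  if (family == "star3") {
    return(build_star_chain(model, N, r))
  }

  # count chains on states i = 0..N (stored at row i+1)
  S <- N + 1L
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(i, j, p) {
    if (p > 0) {
      trip$i <<- c(trip$i, i + 1L)
      trip$j <<- c(trip$j, j + 1L)
      trip$x <<- c(trip$x, p)
    }
  }
  add(0L, 0L, 1)
  add(N, N, 1)
  for (i in seq_len(N - 1L)) {
    wA <- r * i / (r * i + N - i)
    wB <- (N - i) / (r * i + N - i)
    if (family == "complete3") {
      D <- (N - 1) * (N - 2)
      if (model == 1) {
        dn2 <- wB * i * (i - 1) / D
        dn1 <- wB * 2 * i * (N - i - 1) / D
        up1 <- wA * 2 * (i - 1) * (N - i) / D
        up2 <- wA * (N - i) * (N - i - 1) / D
        add(i, i - 2L, dn2); add(i, i - 1L, dn1)
        add(i, i + 1L, up1); add(i, i + 2L, up2)
        add(i, i, 1 - dn2 - dn1 - up1 - up2)
      } else {
        dn1 <- wB * 2 * i * (N - i - 1) / D
        up1 <- wA * 2 * (i - 1) * (N - i) / D
        add(i, i - 1L, dn1); add(i, i + 1L, up1)
        add(i, i, 1 - dn1 - up1)
      }
    } else { # cyclic3, model 1, consecutive-block states
      if (i == 1L) {
        dn1 <- 2 / (r + N - 1)
        up2 <- r / (r + N - 1)
        add(1L, 0L, dn1); add(1L, 3L, up2)
        add(1L, 1L, 1 - dn1 - up2)
      } else if (i == N - 1L) {
        dn2 <- 1 / (r * (N - 1) + 1)
        up1 <- 2 * r / (r * (N - 1) + 1)
        add(i, i - 2L, dn2); add(i, N, up1)
        add(i, i, 1 - dn2 - up1)
      } else {
        den <- 3 * (r * i + N - i)
        add(i, i - 2L, 2 / den); add(i, i - 1L, 4 / den)
        add(i, i + 1L, 4 * r / den); add(i, i + 2L, 2 * r / den)
        add(i, i, 1 - (2 + 4 + 4 * r + 2 * r) / den)
      }
    }
  }
  P <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(S, S))
  states <- data.frame(state = seq_len(S), mutants = 0:N)
  new_reduced_chain(family, model, N, r, P, states,
                    absorbing = c(1L, S), fixation_state = S)
}

# star 3-uniform reduced chain over states (i1, i2): i1 = hub type (1 = mutant),
# i2 = mutant leaf count among the n = N - 1 leaves. Ordering: (0,0)..(0,n),
# (1,0)..(1,n); all-mutant state (1,n) is last. Transitions are derived from
# the model definitions; the leaf picked as reproduction partner is uniform
# among the n - 1 leaves sharing a hyperedge with the parent leaf, and the hub
# is in every hyperedge.
build_star_chain <- function(model, N, r) {
  n <- N - 1L
  S <- 2L * N
  idx <- function(i1, i2) i1 * N + i2 + 1L
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(from, to, p) {
    if (p > 0) {
      trip$i <<- c(trip$i, from); trip$j <<- c(trip$j, to); trip$x <<- c(trip$x, p)
    }
  }
  pair_k <- function(i2, k) {
    # probability a uniform pair of leaves contains exactly k mutants
    choose(i2, k) * choose(n - i2, 2 - k) / choose(n, 2)
  }
  for (i1 in 0:1) {
    for (i2 in 0:n) {
      from <- idx(i1, i2)
      if ((i1 == 0L && i2 == 0L) || (i1 == 1L && i2 == n)) {
        add(from, from, 1)
        next
      }
      i <- i1 + i2
      FW <- r * i + (N - i)
      stay <- 0
      wh <- (if (i1 == 1L) r else 1) / FW
      for (k in 0:2) {
        hk <- pair_k(i2, k)
        if (hk <= 0) next
        if (model == 1) {
          to_i2 <- if (i1 == 1L) i2 + (2L - k) else i2 - k
        } else {
          # majority rule in a size-3 hyperedge: the hub needs one ally in the pair
          to_i2 <- if (i1 == 1L && k == 1L) i2 + 1L
                   else if (i1 == 0L && k == 1L) i2 - 1L
                   else i2
        }
        if (to_i2 == i2) stay <- stay + wh * hk else add(from, idx(i1, to_i2), wh * hk)
      }
      if (i2 > 0L) { # mutant leaf as parent
        wa <- r * i2 / FW
        pA <- (i2 - 1) / (n - 1); pB <- (n - i2) / (n - 1)
        if (model == 1) {
          if (i1 == 1L) {
            stay <- stay + wa * pA
            add(from, idx(1L, i2 + 1L), wa * pB)
          } else {
            add(from, idx(1L, i2), wa * pA)
            add(from, idx(1L, i2 + 1L), wa * pB)
          }
        } else {
          if (i1 == 1L) {
            add(from, idx(1L, i2 + 1L), wa * pB)
            stay <- stay + wa * pA
          } else {
            add(from, idx(1L, i2), wa * pA) # partner leaf mutant: majority, hub flips
            stay <- stay + wa * pB          # both others resident: minority parent
          }
        }
      }
      if (n - i2 > 0L) { # resident leaf as parent
        wb <- (n - i2) / FW
        pA <- i2 / (n - 1); pB <- (n - 1 - i2) / (n - 1)
        if (model == 1) {
          if (i1 == 0L) {
            add(from, idx(0L, i2 - 1L), wb * pA)
            stay <- stay + wb * pB
          } else {
            add(from, idx(0L, i2 - 1L), wb * pA)
            add(from, idx(0L, i2), wb * pB)
          }
        } else {
          if (i1 == 0L) {
            add(from, idx(0L, i2 - 1L), wb * pA)
            stay <- stay + wb * pB
          } else {
            add(from, idx(0L, i2), wb * pB) # partner resident: majority, hub flips
            stay <- stay + wb * pA          # both others mutant: minority parent
          }
        }
      }
      add(from, from, stay)
    }
  }
  P <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(S, S))
  states <- data.frame(
    state = seq_len(S),
    hub = rep(0:1, each = N),
    mutant_leaves = rep(0:n, times = 2)
  )
  states$mutants <- states$hub + states$mutant_leaves
  new_reduced_chain("star3", model, N, r, P, states,
                    absorbing = c(idx(0L, 0L), idx(1L, n)),
                    fixation_state = idx(1L, n))
}

new_reduced_chain <- function(family, model, N, r, P, states, absorbing,
                              fixation_state) {
  rs <- Matrix::rowSums(P)
  if (max(abs(rs - 1)) > 1e-12) {
    stop("internal error: reduced chain rows do not sum to 1 (max dev ",
         format(max(abs(rs - 1))), ")")
  }
  structure(
    list(family = family, model = model, N = N, r = r, P = P, states = states,
         absorbing = absorbing, fixation_state = fixation_state),
    class = "reduced_chain"
  )
}

#' @export
print.reduced_chain <- function(x, ...) {
  cat("<reduced_chain> ", x$family, ", model ", x$model, ", N = ", x$N,
      ", r = ", format(x$r), ", ", nrow(x$P), " states\n", sep = "")
  invisible(x)
}

#' Tidy a reduced chain into its nonzero transitions
#'
#' @param x a `reduced_chain`.
#' @param ... unused.
#' @return a tibble with columns `from`, `to` (state indices) and `prob`.
#' @importFrom generics tidy
#' @export
tidy.reduced_chain <- function(x, ...) {
  Ts <- Matrix::summary(methods::as(x$P, "TsparseMatrix"))
  tibble::tibble(from = Ts$i, to = Ts$j, prob = Ts$x) |>
    dplyr::arrange(.data$from, .data$to)
}
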