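#' Exact fixation probabilities over all 2^N type configurations
#'
#' Builds the full transition kernel of the evolutionary dynamics on an
#' arbitrary connected hypergraph directly from the model definition: the
#' parent is drawn with probability proportional to fitness (`r` for mutants,
#' 1 for residents), a hyperedge is drawn uniformly from the parent's
#' incidence multiset, and the co-members are converted unconditionally
#' (model 1) or only under a strict majority of the parent's type in the
#' hyperedge (model 2). Absorption probabilities at the all-mutant and
#' all-resident configurations are then solved exactly.
#'
#' Under model 2 the chain can possess closed recurrent classes other than
#' the two unanimity states (the dynamics then never fixates from some
#' starts). These are detected by strongly-connected-component analysis of
#' the positive-transition graph; every closed class other than the
#' all-mutant singleton gets all-mutant absorption probability 0, and the
#' all-resident absorption column is handled symmetrically, so
#' `prob_mutant + prob_resident < 1` flags starts with positive probability
#' of never fixating.
#'
#' This solver is exponential in `N` and capped at `N <= 14`; it exists as an
#' oracle for the reduced chains and the simulator, not as a production path.
#'
#' @param H a connected `hypergraph` with every node in at least one
#'   hyperedge.
#' @param model 1 or 2.
#' @param r relative fitness (`> 0`), scalar.
#' @param i mutant count for uniform initialization: the result averages the
#'   per-state probabilities over all `choose(N, i)` placements of `i`
#'   mutants. Exactly one of `i` and `mutants` must be given.
#' @param mutants integer vector of node indices for a specific start.
#' @return an object of class `brute_force_solution`: `probability` (fixation
#'   probability of the mutant for the requested start), `prob_resident`
#'   (absorption at all-resident), `x_mutant` and `x_resident` (per-state
#'   absorption vectors over all `2^N` states, indexed by the bitmask of
#'   mutant nodes plus one), `never_fix` (probability of no fixation), and
#'   the inputs.
#' @examples
#' H <- hypergraph(list(c(1, 2, 3)))
#' brute_force_fixation(H, 1, 2, i = 1)$probability # r/(r+2) = 1/2
#' @export
brute_force_fixation <- function(H, model, r, i = NULL, mutants = NULL) {
  stopifnot(inherits(H, "hypergraph"), model %in% c(1, 2), length(r) == 1L)
  if (r <= 0) stop("relative fitness r must be positive")
  N <- H$n
  if (N > 14L) stop("brute force is capped at N <= 14 (2^N states); got N = ", N)
  if (!is_connected_hypergraph(H)) stop("hypergraph must be connected")
  prof <- degree_size_profile(H)
  if (any(prof$degrees == 0L)) stop("every node must belong to a hyperedge")

  S <- 2L^N
  states <- 0:(S - 1L)
  full <- S - 1L
  pc <- integer(S)
  for (b in 0:(N - 1L)) {
    pc[bitwAnd(states, bitwShiftL(1L, b)) > 0L] <- pc[bitwAnd(states, bitwShiftL(1L, b)) > 0L] + 1L
  }
  fit_tot <- r * pc + (N - pc)

  ii <- vector("list", 0); jj <- vector("list", 0); xx <- vector("list", 0)
  masks <- vapply(H$hyperedges, function(e) sum(bitwShiftL(1L, e - 1L)), numeric(1))
  sizes <- lengths(H$hyperedges)
  inc <- incidence_list(H)
  for (v in seq_len(N)) {
    vbit <- bitwShiftL(1L, v - 1L)
    pA <- bitwAnd(states, vbit) > 0L
    w <- ifelse(pA, r, 1) / (fit_tot * prof$degrees[v])
    for (k in inc[[v]]) {
      mk <- as.integer(masks[k])
      if (model == 1) {
        snew <- ifelse(pA, bitwOr(states, mk), bitwAnd(states, bitwXor(full, mk)))
      } else {
        inA <- pc[bitwAnd(states, mk) + 1L]
        maj <- ifelse(pA, 2L * inA > sizes[k], 2L * (sizes[k] - inA) > sizes[k])
        snew <- ifelse(maj,
                       ifelse(pA, bitwOr(states, mk), bitwAnd(states, bitwXor(full, mk))),
                       states)
      }
      ii[[length(ii) + 1L]] <- states + 1L
      jj[[length(jj) + 1L]] <- snew + 1L
      xx[[length(xx) + 1L]] <- w
    }
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(S, S))
  # unanimity states are absorbing by definition; enforce identity rows
  P[1L, ] <- 0; P[1L, 1L] <- 1
  P[S, ] <- 0; P[S, S] <- 1

  x_mut <- absorption_target(P, target = S)
  x_res <- absorption_target(P, target = 1L)

  if (is.null(i) == is.null(mutants)) {
    stop("give exactly one of `i` (uniform initialization) or `mutants`")
  }
  if (!is.null(i)) {
    i <- as.integer(i)
    if (i < 0L || i > N) stop("mutant count i must be in 0..N")
    sel <- which(pc == i)
  } else {
    mutants <- as.integer(mutants)
    if (any(mutants < 1L | mutants > N) || anyDuplicated(mutants)) {
      stop("`mutants` must be a set of distinct node indices")
    }
    sel <- sum(bitwShiftL(1L, mutants - 1L)) + 1L
  }
  structure(
    list(probability = mean(x_mut[sel]),
         prob_resident = mean(x_res[sel]),
         never_fix = 1 - mean(x_mut[sel]) - mean(x_res[sel]),
         x_mutant = x_mut, x_resident = x_res,
         H = H, model = model, r = r, i = i, mutants = mutants),
    class = "brute_force_solution"
  )
}

# Absorption probability at `target` for every state of a finite chain that
# may contain closed classes besides the absorbing unanimity states. States
# in a closed class not containing the target get probability 0 there; the
# remaining (transient) states are solved via (I - P_TT) x_T = P_TK x_K.
absorption_target <- function(P, target) {
  S <- nrow(P)
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # a strong component is closed iff no positive transition leaves it
  Ts <- Matrix::summary(methods::as(P, "TsparseMatrix"))
  leaves <- Ts$x > 0 & memb[Ts$i] != memb[Ts$j]
  open_comp <- unique(memb[Ts$i[leaves]])
  closed <- setdiff(seq_len(comp$no), open_comp)
  x <- rep(NA_real_, S)
  in_closed <- memb %in% closed
  x[in_closed] <- 0
  x[target] <- 1 # the target unanimity state is its own closed class
  transient <- which(!in_closed)
  if (length(transient)) {
    Ptt <- P[transient, transient, drop = FALSE]
    known <- which(in_closed)
    rhs <- as.numeric(P[transient, known, drop = FALSE] %*% x[known])
    A <- Matrix::Diagonal(length(transient)) - Ptt
    x[transient] <- as.numeric(Matrix::solve(A, rhs))
  }
  if (min(x) < -1e-12 || max(x) > 1 + 1e-12) {
    stop("brute-force absorption probabilities violate [0, 1]")
  }
  pmin(pmax(x, 0), 1)
}

#' @export
print.brute_force_solution <- function(x, ...) {
  cat("<brute_force_solution> N = ", x$H$n, ", model ", x$model,
      ", r = ", format(x$r), "\n", sep = "")
  cat("  P(mutant fixation)   = ", format(x$probability), "\n", sep = "")
  cat("  P(resident fixation) = ", format(x$prob_resident), "\n", sep = "")
  if (x$never_fix > 1e-12) {
    cat("  P(never fixates)     = ", format(x$never_fix), "\n", sep = "")
  }
  invisible(x)
}
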