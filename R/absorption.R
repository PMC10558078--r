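#' Solve the absorption system of a reduced chain
#'
#' Given the reduced transition matrix P, the fixation probabilities x per
#' reduced state satisfy x = P x with boundary values 0 at the all-resident
#' state and 1 at the all-mutant state. Equivalently M x = b, where M is P
#' with 1 subtracted from the diagonal of every non-absorbing row, the
#' absorbing rows replaced by identity rows, and b the indicator of the
#' all-mutant state.
#'
#' @param chain a [build_reduced_chain()] result.
#' @param method `"sparse"` (default; sparse LU, handles every structure
#'   including the star chains), `"dense"` (LAPACK dense solve, used as an
#'   independent oracle in tests), or `"ptrans"` (hand-written pentadiagonal
#'   elimination in the PTRANS family, valid for the banded count chains).
#' @return an object of class `absorption_solution`: the `chain`, the solved
#'   vector `x` (one probability per reduced state, in `[0, 1]`), the method
#'   and the residual `max|Mx - b|`. Solutions violating `[0, 1]` by more
#'   than 1e-12 raise an error rather than being clipped.
#' @examples
#' sol <- solve_absorption(build_reduced_chain("complete3", 1, 4, 1))
#' sol$x # 0, 1/4, 1/2, 3/4, 1 under neutral drift
#' @export
solve_absorption <- function(chain, method = c("sparse", "dense", "ptrans")) {
  method <- match.arg(method)
  stopifnot(inherits(chain, "reduced_chain"))
  S <- nrow(chain$P)
  M <- chain$P
  Matrix::diag(M) <- Matrix::diag(M) - 1
  for (a in chain$absorbing) {
    M[a, ] <- 0
    M[a, a] <- 1
  }
  b <- numeric(S)
  b[chain$fixation_state] <- 1
  x <- switch(method,
    sparse = as.numeric(Matrix::solve(M, b)),
    dense = as.numeric(solve(as.matrix(M), b)),
    ptrans = {
      bw <- matrix_bandwidth(M)
      if (bw > 2L) stop("ptrans method requires a pentadiagonal system; ",
                        "this chain has bandwidth ", bw)
      ptrans_solve(as.matrix(M), b)
    }
  )
  resid <- max(abs(as.numeric(M %*% x) - b))
  if (resid > 1e-10) {
    stop("absorption solve residual ", format(resid), " exceeds 1e-10; ",
         "the system may be ill-conditioned (rcond ~ ",
         format(Matrix::rcond(methods::as(M, "generalMatrix"))), ")")
  }
  if (min(x) < -1e-12 || max(x) > 1 + 1e-12) {
    stop("absorption probabilities violate [0, 1] beyond 1e-12 slack")
  }
  x <- pmin(pmax(x, 0), 1)
  structure(
    list(chain = chain, x = x, method = method, residual = resid),
    class = "absorption_solution"
  )
}

matrix_bandwidth <- function(M) {
  Ts <- Matrix::summary(methods::as(M, "TsparseMatrix"))
  nz <- Ts$x != 0
  if (!any(nz)) return(0L)
  max(abs(Ts$i[nz] - Ts$j[nz]))
}

# Pentadiagonal Gaussian elimination without pivoting (PTRANS-I scheme):
# single forward sweep computing multipliers, then back substitution.
# A is a dense matrix with at most two off-diagonals on each side.
ptrans_solve <- function(A, y) {
  n <- length(y)
  stopifnot(n >= 4)
  d <- diag(A)
  a <- c(A[cbind(1:(n - 1), 2:n)], 0)            # first superdiagonal a[i] = A[i, i+1]
  b <- c(A[cbind(1:(n - 2), 3:n)], 0, 0)         # second superdiagonal
  cc <- c(0, A[cbind(2:n, 1:(n - 1))])           # first subdiagonal c[i] = A[i, i-1]
  e <- c(0, 0, A[cbind(3:n, 1:(n - 2))])         # second subdiagonal
  mu <- numeric(n); al <- numeric(n); be <- numeric(n); z <- numeric(n)
  ga <- numeric(n)
  mu[1] <- d[1]
  if (mu[1] == 0) stop("ptrans: zero pivot")
  al[1] <- a[1] / mu[1]; be[1] <- b[1] / mu[1]; z[1] <- y[1] / mu[1]
  ga[2] <- cc[2]
  mu[2] <- d[2] - al[1] * ga[2]
  if (mu[2] == 0) stop("ptrans: zero pivot")
  al[2] <- (a[2] - be[1] * ga[2]) / mu[2]
  be[2] <- b[2] / mu[2]
  z[2] <- (y[2] - z[1] * ga[2]) / mu[2]
  if (n >= 3) {
    for (i in 3:n) {
      ga[i] <- cc[i] - al[i - 2] * e[i]
      mu[i] <- d[i] - be[i - 2] * e[i] - al[i - 1] * ga[i]
      if (mu[i] == 0) stop("ptrans: zero pivot")
      if (i <= n - 1) al[i] <- (a[i] - be[i - 1] * ga[i]) / mu[i]
      if (i <= n - 2) be[i] <- b[i] / mu[i]
      z[i] <- (y[i] - z[i - 2] * e[i] - z[i - 1] * ga[i]) / mu[i]
    }
  }
  x <- numeric(n)
  x[n] <- z[n]
  if (n >= 2) x[n - 1] <- z[n - 1] - al[n - 1] * x[n]
  if (n >= 3) {
    for (i in (n - 2):1) x[i] <- z[i] - al[i] * x[i + 1] - be[i] * x[i + 2]
  }
  x
}

#' @export
print.absorption_solution <- function(x, ...) {
  cat("<absorption_solution> ", x$chain$family, ", model ", x$chain$model,
      ", N = ", x$chain$N, ", r = ", format(x$chain$r),
      " (", x$method, ", residual ", format(x$residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy an absorption solution
#'
#' @param x an `absorption_solution`.
#' @param ... unused.
#' @return a tibble with the reduced-state descriptors and the fixation
#'   probability `x` of the mutant type from each state.
#' @export
tidy.absorption_solution <- function(x, ...) {
  out <- tibble::as_tibble(x$chain$states)
  out$x <- x$x
  out
}

#' Fixation probability from an absorption solution
#'
#' For the count chains (complete, cyclic) this reads off the probability at
#' mutant count `i`. For the star chains it applies the uniform-initialization
#' mixture over hub/leaf placements, see [star_uniform_mix()].
#'
#' @param sol an `absorption_solution`.
#' @param i initial mutant count.
#' @return fixation probability of the mutant type under uniform placement of
#'   `i` initial mutants.
#' @export
fixation_from_solution <- function(sol, i) {
  chain <- sol$chain
  stopifnot(i >= 0, i <= chain$N)
  if (chain$family == "star3") {
    if (i == 0) return(0)
    if (i == chain$N) return(1)
    return(star_uniform_mix(sol, i))
  }
  sol$x[i + 1L]
}

#' Uniform-initialization mixture for the star family
#'
#' With `i` mutants placed uniformly at random on the star 3-uniform
#' hypergraph, the hub is a mutant in `i/N` of the placements. The fixation
#' probability is therefore
#' \deqn{x_i = \frac{i}{N}\,\tilde x(1, i-1) + \frac{N-i}{N}\,\tilde x(0, i),}
#' where \eqn{\tilde x(i_1, i_2)} is the per-state solution with hub type
#' \eqn{i_1} and \eqn{i_2} mutant leaves.
#'
#' @param sol an `absorption_solution` for a star chain, or the raw
#'   \eqn{\tilde x} vector in the chain's state order.
#' @param i initial mutant count, `1 <= i <= N - 1`.
#' @param N node count; required when `sol` is a raw vector.
#' @return mixed fixation probability.
#' @export
star_uniform_mix <- function(sol, i, N = NULL) {
  if (inherits(sol, "absorption_solution")) {
    if (sol$chain$family != "star3") stop("star_uniform_mix needs a star3 solution")
    N <- sol$chain$N
    xt <- sol$x
  } else {
    if (is.null(N)) stop("N is required when passing a raw state vector")
    xt <- sol
    if (length(xt) != 2L * N) stop("state vector must have length 2N")
  }
  if (i < 1 || i > N - 1) stop("i must be between 1 and N - 1")
  # ordering (0,0)..(0,N-1), (1,0)..(1,N-1)
  x_hubA <- xt[N + i]      # (1, i - 1)
  x_hubB <- xt[i + 1L]     # (0, i)
  (i / N) * x_hubA + ((N - i) / N) * x_hubB
}
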