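#' Closed-form fixation probabilities for the symmetric families
#'
#' Evaluates the exact rational-function fixation probabilities known for the
#' three 3-uniform families at small size (and, where available, general N).
#' Coverage:
#' \itemize{
#' \item model 1, `i = 1`: all three families at `N` in 4, 5;
#' \item model 2, `i = 2`: complete family at any `N >= 4` (and
#'   `i` in `2:(N-2)` via the telescoping product over the odds ratios
#'   \eqn{\gamma_k = p_{k,k-1}/p_{k,k+1}}); cyclic family at any `N >= 4`;
#'   star family at `N` in 4, 5.
#' }
#' Out-of-coverage requests raise a not-implemented error; use
#' [solve_absorption()] or [brute_force_fixation()] instead.
#'
#' Key special values: the complete family under model 2 gives
#' \eqn{x_2 = (1 + 1/r)^{3-N}} (so \eqn{2^{3-N}} at `r = 1`); the cyclic
#' family under model 2 gives \eqn{x_2 = 14/[5(N-1)(N-2)]} at `r = 1`; the
#' star family with `N = 5` under model 2 gives `9/35` at `r = 1`.
#'
#' @param family `"complete3"`, `"cyclic3"` or `"star3"`.
#' @param model 1 or 2.
#' @param N node count.
#' @param r relative fitness (`> 0`). Vectorized.
#' @param i initial mutant count.
#' @return fixation probability, same length as `r`.
#' @examples
#' closed_form_fixation("complete3", 1, 4, 2, 1) # r^2/(r+1)^2 = 4/9
#' closed_form_fixation("star3", 2, 5, 1, 2)     # 9/35
#' @export
closed_form_fixation <- function(family = c("complete3", "cyclic3", "star3"),
                                 model, N, r, i) {
  family <- match.arg(family)
  stopifnot(model %in% c(1, 2))
  if (any(r <= 0)) stop("relative fitness r must be positive")
  N <- as.integer(N)
  uncovered <- function() {
    stop("no printed closed form for (", family, ", model ", model,
         ", N = ", N, ", i = ", i, "); use solve_absorption() or ",
         "brute_force_fixation()")
  }
  if (model == 1) {
    if (i != 1) uncovered()
    if (family == "complete3") {
      if (N == 4) return(r^2 / (r^2 + 2 * r + 1))
      if (N == 5) return(r^2 * (8 * r^2 + 12 * r + 1) /
                           (8 * r^4 + 28 * r^3 + 33 * r^2 + 28 * r + 8))
      uncovered()
    }
    if (family == "cyclic3") {
      if (N == 4) return(r^2 / (r^2 + 2 * r + 1))
      if (N == 5) return(r^2 * (6 * r^2 + 8 * r + 1) /
                           (6 * r^4 + 20 * r^3 + 23 * r^2 + 20 * r + 6))
      uncovered()
    }
    # star3
    if (N == 4) {
      return(r^2 * (3 * r + 5) / (4 * (3 * r^3 + 14 * r^2 + 18 * r + 9)) +
               9 * r^2 / (4 * (3 * r^2 + 5 * r + 3)))
    }
    if (N == 5) {
      return(r^2 * (72 * r^3 + 202 * r^2 + 145 * r + 6) /
               (5 * (72 * r^5 + 490 * r^4 + 1025 * r^3 + 1070 * r^2 + 880 * r + 288)) +
             4 * r^2 * (72 * r^2 + 94 * r + 4) /
               (5 * (72 * r^4 + 202 * r^3 + 217 * r^2 + 202 * r + 72)))
    }
    uncovered()
  }
  # model 2
  if (family == "complete3") {
    if (N < 4 || i < 2 || i > N - 2) uncovered()
    return(complete3_m2_closed(N, r, i))
  }
  if (family == "cyclic3") {
    if (i != 2 || N < 4) uncovered()
    return(cyclic3_m2_x2(N, r))
  }
  # star3
  if (i != 2) uncovered()
  if (N == 4) return(5 * r / (2 * (5 * r + 3)) + 3 * r / (2 * (3 * r + 5)))
  if (N == 5) return(6 * (r^3 + 3 * r^2) / (5 * (3 * r^3 + 13 * r^2 + 15 * r + 4)) +
                       3 * r^2 / (5 * (r^2 + 3 * r + 1)))
  uncovered()
}

# complete 3-uniform, model 2: x_2 = (1 + 1/r)^(3 - N); for i > 2,
# x_i = x_2 (1 + sum_{j=2}^{i-1} prod_{k=2}^{j} gamma_k) with
# gamma_k = (N - k - 1) / (r (k - 1)). The cumulative products are built
# iteratively so no large intermediate binomial blows up.
complete3_m2_closed <- function(N, r, i) {
  x2 <- (1 + 1 / r)^(3 - N)
  if (i == 2) return(x2)
  acc <- 1
  prodk <- rep(1, length(r))
  for (j in 2:(i - 1)) {
    prodk <- prodk * (N - j - 1) / (r * (j - 1))
    acc <- acc + prodk
  }
  x2 * acc
}

# cyclic 3-uniform, model 2, i = 2 under uniform initialization.
# N = 4 branch: r / (1 + r). N >= 5 branch:
# (2/(N-1)) { (1 - 1/r)/(1 - r^-(N-2)) + (r - 1/r)/((r+4)(1 - r^-(N-2))) },
# with the r = 1 limit 14 / [5 (N-1) (N-2)] evaluated explicitly.
cyclic3_m2_x2 <- function(N, r) {
  if (N == 4) return(r / (1 + r))
  out <- numeric(length(r))
  near1 <- abs(r - 1) < 1e-9
  out[near1] <- 14 / (5 * (N - 1) * (N - 2))
  rr <- r[!near1]
  denom <- 1 - rr^(-(N - 2))
  out[!near1] <- (2 / (N - 1)) *
    ((1 - 1 / rr) / denom + (rr - 1 / rr) / ((rr + 4) * denom))
  out
}
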