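#' Moran-process fixation probability
#'
#' Fixation probability of a mutant type with relative fitness `r` in a
#' well-mixed population of size `N` under birth-death updating, starting
#' from `i` mutants:
#' \deqn{x_i = \frac{1 - r^{-i}}{1 - r^{-N}},}
#' with the neutral limit \eqn{x_i = i/N} at \eqn{r = 1}. This is the
#' baseline against which amplification and suppression of selection are
#' judged.
#'
#' @param N population size (`>= 2`).
#' @param r relative fitness of the mutant (`> 0`). Vectorized.
#' @param i initial mutant count in `0:N`.
#' @return fixation probability, same length as `r`.
#' @examples
#' moran_fixation(5, 1, 2) # 2/5
#' moran_fixation(4, 2, 1) # 8/15
#' @export
moran_fixation <- function(N, r, i) {
  stopifnot(N >= 2, i >= 0, i <= N)
  if (any(r <= 0)) stop("relative fitness r must be positive")
  out <- numeric(length(r))
  near1 <- abs(r - 1) < 1e-12
  out[near1] <- i / N
  rr <- r[!near1]
  # expm1-based form is stable for r close to (but not at) 1
  out[!near1] <- expm1(-i * log(rr)) / expm1(-N * log(rr))
  if (i == 0) out[] <- 0
  if (i == N) out[] <- 1
  out
}
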