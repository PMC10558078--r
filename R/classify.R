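#' Classify a structure as amplifier or suppressor of selection
#'
#' Compares a fixation curve against the Moran baseline. The comparison is
#' meaningful only if the curve passes the neutral anchor `x(1) = i/N`
#' (model 2 generally fails it, in which case the verdict is
#' `not_comparable`, reported alongside the conventional phrase "neither
#' amplifier nor suppressor"). Otherwise the per-point signs of
#' `x(r) - x_Moran(r)` decide. A point carries a sign only when its deviation
#' is resolvable: beyond `tol` for exact curves, Moran outside the 95%
#' confidence interval for simulated ones. Both fixation probabilities decay
#' like `r^{-N}` below `r = 1`, so at large `N` points far from `r = 1` are
#' numerically indistinguishable and stay neutral; include grid points close
#' to 1 there.
#' \itemize{
#' \item `suppressor`: every signed point is below Moran for `r > 1` and
#'   above it for `r < 1`, with at least one signed point on each side;
#' \item `amplifier`: the reverse pattern;
#' \item `equivalent`: no signed point anywhere (`within_noise = TRUE` when
#'   that is due to simulation uncertainty);
#' \item `neither`: any other sign pattern.
#' }
#'
#' @param curve a `fixation_curve` containing `r = 1` and at least three
#'   points on each side of it.
#' @param N population size; defaults to the curve attribute.
#' @param i initial mutant count; defaults to the curve attribute.
#' @param tol numeric tolerance separating solver noise from real deviation
#'   (exact curves); default 1e-9.
#' @return a list of class `selection_verdict`: `classification`,
#'   `anchor_ok`, `anchor_value`, `tol`, `baseline`, `within_noise` and the
#'   per-point tibble `evidence` (`r`, `x`, `moran`, `delta`, `sign`).
#' @examples
#' cv <- fixation_curve("complete3", 1, i = 1, N = 20)
#' classify_selection(cv)$classification # "suppressor"
#' @export
classify_selection <- function(curve, N = attr(curve, "N"),
                               i = attr(curve, "i"), tol = 1e-9) {
  stopifnot(inherits(curve, "fixation_curve") || is.data.frame(curve))
  if (is.null(N) || is.null(i)) stop("N and i must be supplied or present as attributes")
  at1 <- which(abs(curve$r - 1) < 1e-12)
  if (length(at1) == 0L) stop("the fitness grid must contain r = 1")
  if (sum(curve$r < 1) < 3 || sum(curve$r > 1) < 3) {
    stop("need at least 3 grid points on each side of r = 1")
  }
  simulated <- "ci_low" %in% names(curve) && any(curve$method == "simulation")
  moran <- moran_fixation(N, curve$r, i)
  delta <- curve$x - moran
  if (simulated) {
    signed <- moran < curve$ci_low | moran > curve$ci_high
    sgn <- ifelse(signed, sign(delta), 0)
  } else {
    sgn <- ifelse(abs(delta) <= tol, 0, sign(delta))
  }
  evidence <- tibble::tibble(r = curve$r, x = curve$x, moran = moran,
                             delta = delta, sign = sgn)
  anchor_value <- curve$x[at1[1]]
  anchor_ok <- if (simulated) {
    i / N >= curve$ci_low[at1[1]] && i / N <= curve$ci_high[at1[1]]
  } else {
    abs(anchor_value - i / N) <= tol
  }
  # A point is "signed" when its deviation is resolvable (beyond tol for
  # exact curves, Moran outside the CI for simulated ones). Unresolvable
  # points cannot contradict a verdict, but a verdict needs at least one
  # signed point on each side of r = 1: fixation probabilities decay so fast
  # below r = 1 at large N that grid points far from 1 carry no usable sign.
  lo <- sgn[curve$r < 1]; hi <- sgn[curve$r > 1]
  both_sides <- any(lo != 0) && any(hi != 0)
  within_noise <- FALSE
  classification <- if (!anchor_ok) {
    "not_comparable"
  } else if (all(sgn == 0)) {
    within_noise <- simulated
    "equivalent"
  } else if (both_sides && all(lo >= 0) && all(hi <= 0)) {
    "suppressor"
  } else if (both_sides && all(lo <= 0) && all(hi >= 0)) {
    "amplifier"
  } else {
    "neither"
  }
  structure(
    list(classification = classification, anchor_ok = anchor_ok,
         anchor_value = anchor_value, expected_anchor = i / N, tol = tol,
         baseline = sprintf("Moran process, N = %d, i = %d", N, i),
         within_noise = within_noise, evidence = evidence),
    class = "selection_verdict"
  )
}

#' @export
print.selection_verdict <- function(x, ...) {
  label <- x$classification
  if (label == "not_comparable") {
    label <- paste0(label, " (neither amplifier nor suppressor: x(1) = ",
                    format(x$anchor_value, digits = 6), " differs from ",
                    format(x$expected_anchor, digits = 6), ")")
  }
  cat("<selection_verdict> ", label, "\n", sep = "")
  cat("  baseline: ", x$baseline, "\n", sep = "")
  invisible(x)
}

#' Tidy a selection verdict into its per-point evidence
#'
#' @param x a `selection_verdict`.
#' @param ... unused.
#' @return the evidence tibble with columns `r`, `x`, `moran`, `delta`,
#'   `sign`.
#' @export
tidy.selection_verdict <- function(x, ...) x$evidence

#' Glance at a selection verdict
#'
#' @param x a `selection_verdict`.
#' @param ... unused.
#' @return one-row tibble with the classification, anchor diagnostics and
#'   sign counts.
#' @export
glance.selection_verdict <- function(x, ...) {
  tibble::tibble(
    classification = x$classification,
    anchor_ok = x$anchor_ok,
    anchor_value = x$anchor_value,
    expected_anchor = x$expected_anchor,
    n_below = sum(x$evidence$sign < 0),
    n_above = sum(x$evidence$sign > 0),
    n_tied = sum(x$evidence$sign == 0)
  )
}
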