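#' Run a full fixation experiment from a configuration
#'
#' Drives the standard pipeline end to end: build or load the hypergraph,
#' sweep the fixation probability over a fitness grid by the requested
#' method, classify the result against the Moran baseline, and optionally do
#' the same for the weighted one-mode projection and for a degree- and
#' size-preserving randomization of the hypergraph. Results are returned as
#' tibbles and, when `out_dir` is given, written as CSV (curves) and JSON
#' (verdicts plus a parameter log).
#'
#' @param config a named list with fields:
#'   \describe{
#'   \item{family / file / hypergraph}{exactly one: a family name with `N`, a
#'     hyperedge-list path, or a `hypergraph` object.}
#'   \item{model}{1 or 2 (default 1).}
#'   \item{i}{initial mutant count (default 1 for model 1, 2 for model 2).}
#'   \item{r_values}{fitness grid (default [default_r_grid()]).}
#'   \item{method}{`"auto"`, `"exact"`, `"closed_form"`, `"brute_force"` or
#'     `"simulation"` (default `"auto"` for families, `"simulation"` for
#'     loaded hypergraphs with `N > 14`, `"brute_force"` otherwise).}
#'   \item{runs_per_start, seed, max_steps}{simulation controls.}
#'   \item{projection}{if `TRUE`, also sweep the weighted one-mode
#'     projection.}
#'   \item{randomize}{if `TRUE`, also sweep one randomized replica.}
#'   }
#' @param out_dir optional output directory.
#' @return a list of class `fixation_experiment`: `curve`, `verdict`,
#'   optional `projection_curve`/`projection_verdict`,
#'   `randomized_curve`/`randomized_verdict`, the resolved `config`, and
#'   written file `paths`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  known <- c("family", "file", "hypergraph", "N", "model", "i", "r_values",
             "method", "runs_per_start", "seed", "max_steps", "projection",
             "randomize", "n_swaps")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  src <- c("family", "file", "hypergraph") %in% names(config)
  if (sum(src) != 1L) stop("config needs exactly one of family, file, hypergraph")

  model <- config$model %||% 1
  i <- config$i %||% if (model == 1) 1 else 2
  r_values <- config$r_values %||% default_r_grid()
  seed <- config$seed %||% 1
  runs <- config$runs_per_start %||% 3e3

  if (!is.null(config$family)) {
    H <- make_model_hypergraph(config$family, config$N)
    target <- config$family
    method <- config$method %||% "auto"
  } else {
    H <- if (!is.null(config$file)) read_hyperedge_list(config$file) else config$hypergraph
    target <- if (!is.null(config$file)) config$file else "hypergraph"
    method <- config$method %||% if (H$n <= 14) "brute_force" else "simulation"
    if (method %in% c("exact", "closed_form")) {
      stop("method '", method, "' applies to the symmetric families only; ",
           "use 'brute_force' (N <= 14) or 'simulation' for this hypergraph")
    }
    if (method == "brute_force" && H$n > 14) {
      stop("brute force is infeasible for N = ", H$n,
           " (> 14); use method = 'simulation'")
    }
  }

  sweep <- function(tgt, sweep_seed) {
    if (!is.null(config$family) && is.character(tgt)) {
      fixation_curve(tgt, model, i, r_values, N = config$N, method = method,
                     runs_per_start = runs, seed = sweep_seed,
                     max_steps = config$max_steps)
    } else {
      fixation_curve(tgt, model, i, r_values,
                     method = if (method == "auto") "brute_force" else method,
                     runs_per_start = runs, seed = sweep_seed,
                     max_steps = config$max_steps)
    }
  }

  curve <- sweep(if (!is.null(config$family)) config$family else H, seed)
  result <- list(
    curve = curve,
    verdict = classify_selection(curve),
    config = c(config, list(target = target, model = model, i = i,
                            method = method)),
    paths = character(0)
  )

  if (isTRUE(config$projection)) {
    P <- one_mode_projection(H, weighted = TRUE)
    result$projection_curve <- sweep(P, derive_seed(seed, 101L))
    result$projection_verdict <- classify_selection(result$projection_curve)
  }
  if (isTRUE(config$randomize)) {
    Hr <- randomize_hypergraph(H, n_swaps = config$n_swaps,
                               seed = derive_seed(seed, 202L))
    result$randomized_connected <- is_connected_hypergraph(Hr)
    result$randomized_curve <- sweep(Hr, derive_seed(seed, 303L))
    result$randomized_verdict <- classify_selection(result$randomized_curve)
  }
  class(result) <- "fixation_experiment"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    wr <- function(tbl, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(tbl), p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    wr(curve, "curve.csv")
    if (!is.null(result$projection_curve)) wr(result$projection_curve, "projection_curve.csv")
    if (!is.null(result$randomized_curve)) wr(result$randomized_curve, "randomized_curve.csv")
    verdicts <- list(main = result$verdict$classification)
    if (!is.null(result$projection_verdict)) {
      verdicts$projection <- result$projection_verdict$classification
    }
    if (!is.null(result$randomized_verdict)) {
      verdicts$randomized <- result$randomized_verdict$classification
      verdicts$randomized_connected <- result$randomized_connected
    }
    log <- list(
      target = target, model = model, i = i, N = H$n,
      n_hyperedges = length(H$hyperedges), method = method,
      r_values = r_values, seed = seed, runs_per_start = runs,
      package_version = as.character(utils::packageVersion("hyperfix")),
      r_version = R.version.string
    )
    p <- file.path(out_dir, "verdicts.json")
    jsonlite::write_json(verdicts, p, auto_unbox = TRUE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "log.json")
    jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    result$paths <- paths
  }
  result
}

#' @export
print.fixation_experiment <- function(x, ...) {
  cat("<fixation_experiment> ", x$config$target, ", model ", x$config$model,
      ", i = ", x$config$i, ", method ", x$config$method, "\n", sep = "")
  cat("  verdict: ", x$verdict$classification, "\n", sep = "")
  if (!is.null(x$projection_verdict)) {
    cat("  weighted projection: ", x$projection_verdict$classification, "\n", sep = "")
  }
  if (!is.null(x$randomized_verdict)) {
    cat("  randomized replica: ", x$randomized_verdict$classification, "\n", sep = "")
  }
  invisible(x)
}
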