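#' Construct a hypergraph
#'
#' A hypergraph is a set of `n_nodes` nodes together with an ordered multiset
#' of hyperedges, each hyperedge a set of distinct node indices. Duplicate
#' hyperedges are allowed and carry multiset semantics: a hyperedge listed
#' twice is selected twice as often by the birth-death dynamics, which is how
#' integer edge weights are encoded (see [one_mode_projection()]).
#'
#' @param hyperedges list of integer vectors, each a set of distinct node
#'   indices in `1:n_nodes`.
#' @param n_nodes number of nodes. Defaults to the largest index present.
#' @param labels optional character vector of external node labels, one per
#'   node.
#' @return an object of class `hypergraph` with fields `n`, `hyperedges`
#'   (each sorted increasingly) and `labels`.
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(3, 4, 5), c(4, 5, 6), c(6, 1, 2)))
#' H
#' @export
hypergraph <- function(hyperedges, n_nodes = NULL, labels = NULL) {
  stopifnot(is.list(hyperedges))
  hyperedges <- lapply(hyperedges, function(e) sort(as.integer(e)))
  if (is.null(n_nodes)) {
    n_nodes <- if (length(hyperedges)) max(unlist(hyperedges)) else 0L
  }
  n_nodes <- as.integer(n_nodes)
  H <- structure(
    list(n = n_nodes, hyperedges = hyperedges, labels = labels),
    class = "hypergraph"
  )
  validate_hypergraph(H)
  H
}

#' Validate a hypergraph object
#'
#' Checks the structural invariants: indices in range, no repeated node inside
#' a hyperedge, labels (if any) one per node. Size-1 hyperedges are accepted
#' with a warning: reproduction through them is a no-op since there is no
#' other member to convert.
#'
#' @param H a `hypergraph`.
#' @return `H`, invisibly. Errors on violation.
#' @export
validate_hypergraph <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  if (H$n < 1L) stop("hypergraph must have at least one node")
  for (k in seq_along(H$hyperedges)) {
    e <- H$hyperedges[[k]]
    if (length(e) == 0L) stop("hyperedge ", k, " is empty")
    if (any(e < 1L | e > H$n)) {
      stop("hyperedge ", k, " contains a node index outside 1..", H$n)
    }
    if (anyDuplicated(e)) stop("hyperedge ", k, " contains a repeated node")
  }
  if (any(lengths(H$hyperedges) == 1L)) {
    warning("hypergraph contains size-1 hyperedges; they are inert under the dynamics")
  }
  if (!is.null(H$labels) && length(H$labels) != H$n) {
    stop("labels must have one entry per node")
  }
  invisible(H)
}

#' @export
print.hypergraph <- function(x, ...) {
  sz <- lengths(x$hyperedges)
  cat("<hypergraph> ", x$n, " nodes, ", length(x$hyperedges), " hyperedges",
      if (length(sz)) paste0(" (sizes ", min(sz), "-", max(sz), ")"), "\n", sep = "")
  invisible(x)
}

#' @export
format.hypergraph <- function(x, ...) {
  paste0("hypergraph(", x$n, " nodes, ", length(x$hyperedges), " hyperedges)")
}

#' Node labels of a hypergraph
#'
#' @param H a `hypergraph`.
#' @return character vector of labels; node indices as strings when no
#'   external labels were attached.
#' @export
node_labels <- function(H) {
  if (is.null(H$labels)) as.character(seq_len(H$n)) else H$labels
}

#' Per-node incidence list
#'
#' @param H a `hypergraph`.
#' @return list with one integer vector per node giving the indices of the
#'   hyperedges containing it (with multiplicity, since duplicate hyperedges
#'   are distinct entries of the multiset).
#' @export
incidence_list <- function(H) {
  inc <- vector("list", H$n)
  for (v in seq_len(H$n)) inc[[v]] <- integer(0)
  for (k in seq_along(H$hyperedges)) {
    for (v in H$hyperedges[[k]]) inc[[v]] <- c(inc[[v]], k)
  }
  inc
}

#' Generate one of the symmetric model hypergraph families
#'
#' The three 3-uniform families generalize the complete graph, the cycle and
#' the star: `complete3` takes every 3-node subset as a hyperedge; `cyclic3`
#' takes every three consecutive nodes around a cycle (periodic boundary);
#' `star3` pairs the hub (node 1) with every pair of the `N - 1` leaves.
#' `complete_graph` is the ordinary complete graph, on which model 1 is the
#' Moran process.
#'
#' @param family one of `"complete3"`, `"cyclic3"`, `"star3"`,
#'   `"complete_graph"`.
#' @param N node count; `complete3` needs `N >= 3`, `cyclic3` and `star3`
#'   need `N >= 4`, `complete_graph` needs `N >= 2`.
#' @return a connected `hypergraph`.
#' @examples
#' make_model_hypergraph("complete3", 4)
#' make_model_hypergraph("star3", 5)
#' @export
make_model_hypergraph <- function(family = c("complete3", "cyclic3", "star3", "complete_graph"),
                                  N) {
  family <- match.arg(family)
  N <- as.integer(N)
  min_n <- c(complete3 = 3L, cyclic3 = 4L, star3 = 4L, complete_graph = 2L)[[family]]
  if (N < min_n) {
    stop("family '", family, "' requires N >= ", min_n, " (got ", N, ")")
  }
  edges <- switch(family,
    complete3 = utils::combn(N, 3, simplify = FALSE),
    cyclic3 = lapply(seq_len(N), function(k) sort((c(k, k + 1L, k + 2L) - 1L) %% N + 1L)),
    star3 = {
      pairs <- utils::combn(2:N, 2, simplify = FALSE)
      lapply(pairs, function(p) c(1L, p))
    },
    complete_graph = utils::combn(N, 2, simplify = FALSE)
  )
  hypergraph(edges, n_nodes = N)
}

#' Is a hypergraph connected?
#'
#' Connectivity in the cut sense: for every non-empty proper node subset W
#' some hyperedge intersects both W and its complement. Equivalent to
#' connectivity of the bipartite node-hyperedge incidence graph once every
#' node is reachable; a degree-0 node with `N >= 2` makes the hypergraph
#' disconnected.
#'
#' @param H a `hypergraph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_connected_hypergraph <- function(H) {
  if (H$n == 1L) return(TRUE)
  if (length(H$hyperedges) == 0L) return(FALSE)
  el <- do.call(rbind, lapply(seq_along(H$hyperedges), function(k) {
    cbind(H$hyperedges[[k]], H$n + k)
  }))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, H$n + length(H$hyperedges) - igraph::vcount(g)))
  comp <- igraph::components(g)
  # all N node-vertices in one component
  length(unique(comp$membership[seq_len(H$n)])) == 1L
}

#' Degree and size profile of a hypergraph
#'
#' @param H a `hypergraph`.
#' @return a list with class `degree_size_profile`: `degrees`, the per-node
#'   count of incident hyperedges (duplicates counted), and `sizes`, the
#'   per-hyperedge node count in hyperedge order. The two always satisfy
#'   `sum(degrees) == sum(sizes)`.
#' @export
degree_size_profile <- function(H) {
  degrees <- tabulate(unlist(H$hyperedges), nbins = H$n)
  sizes <- lengths(H$hyperedges)
  structure(list(degrees = degrees, sizes = sizes), class = "degree_size_profile")
}

#' @export
print.degree_size_profile <- function(x, ...) {
  cat("<degree_size_profile> ", length(x$degrees), " nodes, ",
      length(x$sizes), " hyperedges, total incidences ", sum(x$sizes), "\n", sep = "")
  invisible(x)
}

#' One-mode projection of a hypergraph
#'
#' Projects the hypergraph onto a conventional network: two nodes become
#' adjacent iff they share at least one hyperedge. The weighted variant sets
#' the edge weight to the number of shared hyperedges; weights are encoded as
#' duplicated size-2 hyperedges so that the birth-death dynamics, which picks
#' one incident hyperedge uniformly, automatically selects edges with
#' probability proportional to weight.
#'
#' @param H a `hypergraph`.
#' @param weighted if `TRUE` (default) each adjacent pair appears once per
#'   shared hyperedge; if `FALSE`, exactly once.
#' @return a `hypergraph` on the same node set whose hyperedges all have
#'   size 2.
#' @export
one_mode_projection <- function(H, weighted = TRUE) {
  pairs <- list()
  for (e in H$hyperedges) {
    if (length(e) >= 2L) {
      pairs <- c(pairs, utils::combn(e, 2, simplify = FALSE))
    }
  }
  if (length(pairs) == 0L) {
    return(hypergraph(list(), n_nodes = H$n, labels = H$labels))
  }
  key <- vapply(pairs, function(p) paste(p, collapse = "-"), character(1))
  if (!weighted) pairs <- pairs[!duplicated(key)]
  pairs <- pairs[order(vapply(pairs, `[`, integer(1), 1L),
                       vapply(pairs, `[`, integer(1), 2L))]
  hypergraph(pairs, n_nodes = H$n, labels = H$labels)
}

#' Degree- and size-preserving randomization
#'
#' Shuffles the hyperedges by repeated double-edge swaps on the bipartite
#' node-hyperedge incidence structure: two incidences (e1, u) and (e2, v) are
#' picked at random and the nodes exchanged. A proposed swap that would place
#' a node twice in one hyperedge (or swap a node with itself) is rejected and
#' does not count toward `n_swaps`. The per-node degree vector and the
#' per-hyperedge size vector are invariant by construction. Connectivity of
#' the result is not enforced.
#'
#' @param H a `hypergraph`.
#' @param n_swaps number of accepted swaps; default `10 * sum(sizes)`, a
#'   standard mixing heuristic for double-edge-swap randomization.
#' @param seed optional integer seed for reproducibility.
#' @param max_tries cap on proposals; if reached before `n_swaps` acceptances
#'   a warning is issued and the partially shuffled hypergraph is returned.
#' @return a `hypergraph` with the same [degree_size_profile()] as `H`.
#' @export
randomize_hypergraph <- function(H, n_swaps = NULL, seed = NULL, max_tries = NULL) {
  prof <- degree_size_profile(H)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(prof$sizes)
  if (n_swaps == 0L) return(H)
  if (!is.null(seed)) set.seed(seed)
  # flat incidence table: edge index / node for each incidence
  edge_of <- rep(seq_along(H$hyperedges), times = prof$sizes)
  node_of <- unlist(H$hyperedges)
  m <- length(node_of)
  if (m < 2L || length(H$hyperedges) < 2L) {
    warning("no feasible swap; returning the hypergraph unchanged")
    return(H)
  }
  edges <- H$hyperedges
  if (is.null(max_tries)) max_tries <- 200L * n_swaps
  accepted <- 0L
  tries <- 0L
  while (accepted < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    ij <- sample.int(m, 2L)
    e1 <- edge_of[ij[1L]]; e2 <- edge_of[ij[2L]]
    u <- node_of[ij[1L]]; v <- node_of[ij[2L]]
    if (e1 == e2 || u == v) next
    if (v %in% edges[[e1]] || u %in% edges[[e2]]) next
    edges[[e1]] <- sort(c(setdiff(edges[[e1]], u), v))
    edges[[e2]] <- sort(c(setdiff(edges[[e2]], v), u))
    node_of[ij[1L]] <- v
    node_of[ij[2L]] <- u
    accepted <- accepted + 1L
  }
  if (accepted < n_swaps) {
    warning("only ", accepted, " of ", n_swaps, " swaps accepted before the proposal cap")
  }
  out <- hypergraph(edges, n_nodes = H$n, labels = H$labels)
  out
}

#' Read a hypergraph from a hyperedge-list file
#'
#' Plain-text format: one hyperedge per line, whitespace-separated node
#' labels. Blank lines and lines starting with `#` are ignored. Labels are
#' mapped to node indices in order of first appearance and retained.
#'
#' @param path file path.
#' @return a `hypergraph` with `labels` set.
#' @export
read_hyperedge_list <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no hyperedges found in ", path)
  toks <- lapply(lines[keep], function(l) strsplit(trimws(l), "\\s+")[[1]])
  for (j in seq_along(toks)) {
    if (anyDuplicated(toks[[j]])) {
      stop("repeated node label within hyperedge on line ", keep[j], " of ", path)
    }
  }
  labels <- unique(unlist(toks))
  edges <- lapply(toks, function(tk) match(tk, labels))
  hypergraph(edges, n_nodes = length(labels), labels = labels)
}

#' Write a hypergraph to a hyperedge-list file
#'
#' Inverse of [read_hyperedge_list()]: `read(write(H))` restores the node
#' count, the hyperedge multiset and the labels.
#'
#' @param H a `hypergraph`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hyperedge_list <- function(H, path) {
  lab <- node_labels(H)
  lines <- vapply(H$hyperedges, function(e) paste(lab[e], collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random connected hypergraph
#'
#' Samples `n_edges` hyperedges whose sizes are drawn uniformly from `sizes`
#' and whose members are uniform node subsets, rejecting disconnected draws.
#' Intended as a fixture generator for testing exact and stochastic solvers
#' on structures without special symmetry.
#'
#' @param n_nodes node count (`>= 2`).
#' @param n_edges hyperedge count (`>= 1`).
#' @param sizes candidate hyperedge sizes, all in `[2, n_nodes]`.
#' @param seed optional integer seed.
#' @param max_retries attempts before giving up on connectivity.
#' @return a connected `hypergraph`.
#' @export
random_hypergraph <- function(n_nodes, n_edges, sizes = 2:3, seed = NULL,
                              max_retries = 200L) {
  stopifnot(n_nodes >= 2L, n_edges >= 1L, all(sizes >= 2L), all(sizes <= n_nodes))
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    sz <- sizes[sample.int(length(sizes), n_edges, replace = TRUE)]
    edges <- lapply(sz, function(s) sort(sample.int(n_nodes, s)))
    H <- hypergraph(edges, n_nodes = n_nodes)
    if (is_connected_hypergraph(H)) return(H)
  }
  stop("failed to draw a connected hypergraph after ", max_retries,
       " attempts; try a larger n_edges")
}

#' Test two hypergraphs for equality
#'
#' Equality of node count, hyperedge multiset (order-insensitive) and labels.
#'
#' @param a,b `hypergraph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
hypergraph_equal <- function(a, b) {
  if (a$n != b$n) return(FALSE)
  key <- function(H) sort(vapply(H$hyperedges, paste, character(1), collapse = "-"))
  if (!identical(key(a), key(b))) return(FALSE)
  identical(a$labels, b$labels)
}
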