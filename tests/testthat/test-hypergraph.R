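test_that("family generators match their defining combinatorics", {
  H <- make_model_hypergraph("complete3", 4)
  expect_equal(H$n, 4L)
  expect_setequal(
    vapply(H$hyperedges, paste, character(1), collapse = "-"),
    c("1-2-3", "1-2-4", "1-3-4", "2-3-4")
  )

  cy <- make_model_hypergraph("cyclic3", 8)
  expect_length(cy$hyperedges, 8L)
  expect_equal(degree_size_profile(cy)$degrees, rep(3L, 8))

  st <- make_model_hypergraph("star3", 5)
  prof <- degree_size_profile(st)
  expect_length(st$hyperedges, choose(4, 2))
  expect_equal(prof$degrees[1], choose(4, 2)) # hub in every hyperedge
  expect_equal(prof$degrees[-1], rep(3L, 4))  # each leaf pairs with N - 2 others
  expect_true(all(vapply(st$hyperedges, function(e) 1L %in% e, logical(1))))

  kg <- make_model_hypergraph("complete_graph", 6)
  expect_length(kg$hyperedges, choose(6, 2))
  expect_true(all(lengths(kg$hyperedges) == 2L))

  for (fam in c("complete3", "cyclic3", "star3", "complete_graph")) {
    G <- make_model_hypergraph(fam, 6)
    expect_true(is_connected_hypergraph(G))
    p <- degree_size_profile(G)
    expect_equal(sum(p$degrees), sum(p$sizes))
  }
})

test_that("generators reject sizes below the family minimum", {
  expect_error(make_model_hypergraph("complete3", 2), "N >= 3")
  expect_error(make_model_hypergraph("cyclic3", 3), "N >= 4")
  expect_error(make_model_hypergraph("star3", 3), "N >= 4")
  expect_error(make_model_hypergraph("complete_graph", 1), "N >= 2")
})

test_that("hypergraph validation catches malformed input", {
  expect_error(hypergraph(list(c(1, 1, 2)), n_nodes = 3), "repeated node")
  expect_error(hypergraph(list(c(1, 5)), n_nodes = 3), "outside")
  expect_warning(hypergraph(list(1, c(1, 2)), n_nodes = 2), "size-1")
  # duplicate hyperedges are legitimate multiset entries
  H <- hypergraph(list(c(1, 2), c(1, 2)), n_nodes = 2)
  expect_equal(degree_size_profile(H)$degrees, c(2L, 2L))
})

test_that("connectivity follows the cut definition", {
  expect_true(is_connected_hypergraph(hypergraph(list(c(1, 2, 3)), n_nodes = 3)))
  expect_false(is_connected_hypergraph(
    hypergraph(list(c(1, 2), c(3, 4)), n_nodes = 4)
  ))
  # isolated node disconnects even when all hyperedges overlap
  expect_false(is_connected_hypergraph(hypergraph(list(c(1, 2, 3)), n_nodes = 4)))
  expect_true(is_connected_hypergraph(make_model_hypergraph("cyclic3", 8)))
})

test_that("one-mode projection counts shared hyperedges", {
  cy <- make_model_hypergraph("cyclic3", 8)
  W <- one_mode_projection(cy, weighted = TRUE)
  expect_true(all(lengths(W$hyperedges) == 2L))
  # node 1 shares two hyperedges with each cycle neighbor, one at distance 2
  mult <- table(vapply(
    Filter(function(e) 1L %in% e, W$hyperedges),
    function(e) setdiff(e, 1L), integer(1)
  ))
  expect_equal(mult[["2"]], 2L); expect_equal(mult[["8"]], 2L)
  expect_equal(mult[["3"]], 1L); expect_equal(mult[["7"]], 1L)
  expect_equal(unique(degree_size_profile(W)$degrees), 6L)

  # complete family: every pair shares N - 2 hyperedges, so the weighted
  # projection is regular too
  K <- one_mode_projection(make_model_hypergraph("complete3", 6), weighted = TRUE)
  expect_equal(unique(degree_size_profile(K)$degrees), 5L * 4L)

  # unweighted star projection is the complete graph
  U <- one_mode_projection(make_model_hypergraph("star3", 6), weighted = FALSE)
  expect_true(hypergraph_equal(U, make_model_hypergraph("complete_graph", 6)))
})

test_that("randomization preserves the degree/size profile and the seed", {
  H <- random_hypergraph(12, 18, sizes = 2:4, seed = 5)
  before <- degree_size_profile(H)
  R1 <- randomize_hypergraph(H, seed = 7)
  R2 <- randomize_hypergraph(H, seed = 7)
  R3 <- randomize_hypergraph(H, seed = 8)
  expect_equal(degree_size_profile(R1), before)
  expect_true(hypergraph_equal(R1, R2))
  expect_false(hypergraph_equal(R1, R3) && hypergraph_equal(R1, H))
  # zero swaps is the identity
  expect_true(hypergraph_equal(randomize_hypergraph(H, n_swaps = 0), H))
  # a single hyperedge admits no swap
  expect_warning(
    out <- randomize_hypergraph(hypergraph(list(c(1, 2, 3)), n_nodes = 3),
                                n_swaps = 5),
    "swap"
  )
  expect_true(hypergraph_equal(out, hypergraph(list(c(1, 2, 3)), n_nodes = 3)))
})

test_that("hyperedge-list files round-trip with labels", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy", "1 2 3", "3 4 5", "", "4 5 6", "6 1 2"), path)
  H <- read_hyperedge_list(path)
  expect_equal(H$n, 6L)
  expect_length(H$hyperedges, 4L)
  expect_equal(node_labels(H), as.character(1:6))

  out <- withr::local_tempfile(fileext = ".txt")
  write_hyperedge_list(H, out)
  expect_true(hypergraph_equal(read_hyperedge_list(out), H))

  # duplicated line keeps multiset semantics
  writeLines(c("a b", "a b"), path)
  D <- read_hyperedge_list(path)
  expect_equal(D$n, 2L)
  expect_equal(degree_size_profile(D)$degrees, c(2L, 2L))

  writeLines("x y x", path)
  expect_error(read_hyperedge_list(path), "line 1")
  writeLines(c("", "# nothing"), path)
  expect_error(read_hyperedge_list(path), "no hyperedges")
})

test_that("random hypergraphs are connected and reproducible", {
  A <- random_hypergraph(6, 8, sizes = 2:4, seed = 0)
  B <- random_hypergraph(6, 8, sizes = 2:4, seed = 0)
  expect_true(hypergraph_equal(A, B))
  expect_true(is_connected_hypergraph(A))
  expect_length(A$hyperedges, 8L)
  expect_true(all(lengths(A$hyperedges) %in% 2:4))
  expect_true(hypergraph_equal(random_hypergraph(2, 1, sizes = 2, seed = 1),
                               hypergraph(list(c(1, 2)), n_nodes = 2)))
})
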