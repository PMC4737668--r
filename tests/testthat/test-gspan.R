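code_row <- function(i, j, li, le, lj) {
  m <- matrix(as.integer(c(i, j, li, le, lj)), nrow = 1L)
  colnames(m) <- c("i", "j", "li", "le", "lj")
  m
}

test_that("minimum DFS code check orders single edges by label", {
  expect_true(is_minimum_dfs_code(code_row(0, 1, 1, 0, 2)))
  expect_false(is_minimum_dfs_code(code_row(0, 1, 2, 0, 1)))
  expect_true(is_minimum_dfs_code(code_row(0, 1, 3, 0, 3)))
  expect_error(is_minimum_dfs_code(matrix(integer(0), ncol = 5L)), "no edges")
  expect_error(is_minimum_dfs_code(matrix(1:4, 1L)), "malformed")
})

test_that("exactly the minimum code of a labeled triangle passes", {
  # triangle with labels 1,2,3: all 6 full DFS codes, one per start/direction
  codes <- list(
    rbind(code_row(0, 1, 1, 0, 2), code_row(1, 2, 2, 0, 3),
          code_row(2, 0, 3, 0, 1)),
    rbind(code_row(0, 1, 1, 0, 3), code_row(1, 2, 3, 0, 2),
          code_row(2, 0, 2, 0, 1)),
    rbind(code_row(0, 1, 2, 0, 1), code_row(1, 2, 1, 0, 3),
          code_row(2, 0, 3, 0, 2)),
    rbind(code_row(0, 1, 2, 0, 3), code_row(1, 2, 3, 0, 1),
          code_row(2, 0, 1, 0, 2)),
    rbind(code_row(0, 1, 3, 0, 1), code_row(1, 2, 1, 0, 2),
          code_row(2, 0, 2, 0, 3)),
    rbind(code_row(0, 1, 3, 0, 2), code_row(1, 2, 2, 0, 1),
          code_row(2, 0, 1, 0, 3)))
  passes <- vapply(codes, is_minimum_dfs_code, logical(1))
  expect_identical(sum(passes), 1L)
  expect_true(passes[[1]])  # starts at the smallest label pair
  # all encode the same (isomorphic) triangle
  for (cd in codes[-1])
    expect_true(graphs_isomorphic(graph_from_dfs_code(codes[[1]]),
                                  graph_from_dfs_code(cd)))
})

test_that("rightmost extensions match the oracle on small cases", {
  # single vertex in a one-edge dataset: exactly the edge extension
  ds1 <- graph_dataset(list(labeled_graph(c(1, 2), rbind(c(1, 2)))))
  emb <- list("1" = matrix(1L, 1L, 1L))
  exts <- rightmost_extensions(NULL, emb, ds1, root_label = 1L)
  expect_length(exts, 1L)
  expect_equal(unname(exts[[1]]$tuple), c(0L, 1L, 1L, 0L, 2L))
  expect_identical(names(exts[[1]]$maps), "1")

  # pattern saturating a component: no extensions
  ds2 <- graph_dataset(list(labeled_graph(c(1, 2), rbind(c(1, 2))),
                            labeled_graph(c(1, 2), rbind(c(1, 2)))))
  embs <- list("1" = matrix(c(1L, 2L), 1L), "2" = matrix(c(1L, 2L), 1L))
  exts2 <- rightmost_extensions(code_row(0, 1, 1, 0, 2), embs, ds2)
  expect_length(exts2, 0L)

  # path of length 2 inside a labeled 4-cycle: extensions agree with the
  # brute-force one-edge supergraphs (support recomputed by the oracle)
  cyc <- labeled_graph(c(1, 2, 3, 4),
                       rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  ds3 <- graph_dataset(list(cyc))
  code <- rbind(code_row(0, 1, 1, 0, 2), code_row(1, 2, 2, 0, 3))
  emb3 <- list("1" = matrix(c(1L, 2L, 3L), 1L))
  exts3 <- rightmost_extensions(code, emb3, ds3)
  ext_graphs <- lapply(exts3, function(e) graph_from_dfs_code(e$code))
  # oracle: connected 3-edge supergraphs of the path 1-2-3 within the cycle
  oracle <- Filter(function(sg) {
    nrow(sg$edges) == 3L &&
      is_subgraph_isomorphic(graph_from_dfs_code(code), sg)
  }, connected_subgraphs_of(cyc))
  oracle <- oracle[!duplicated(vapply(oracle, iso_invariant_key, character(1)))]
  expect_equal(length(ext_graphs), length(oracle))
  for (og in oracle) {
    expect_true(any(vapply(ext_graphs, graphs_isomorphic, logical(1),
                           g2 = og)))
  }
  for (e in exts3)
    expect_equal(e$support,
                 length(compute_support(graph_from_dfs_code(e$code),
                                        ds3)$support))
})

test_that("enumerate_frequent handles the toy cases", {
  g <- labeled_graph(c(1, 2), rbind(c(1, 2)))
  ds <- graph_dataset(list(g, g, g))
  pats <- enumerate_frequent(ds, 1.0)
  expect_length(pats, 3L)  # vertex(1), vertex(2), edge(1-2)
  sizes <- sort(vapply(pats, function(p) nrow(p$graph$edges), integer(1)))
  expect_identical(sizes, c(0L, 0L, 1L))
  expect_true(all(vapply(pats, function(p)
    identical(p$support, 1:3), logical(1))))

  # frequency filter removes a label present in 1 of 3 graphs
  ds2 <- graph_dataset(list(g, g, labeled_graph(9)))
  pats2 <- enumerate_frequent(ds2, 2 / 3)
  labs <- unlist(lapply(pats2, function(p) p$graph$vlabels))
  expect_false(9 %in% labs)

  expect_error(enumerate_frequent(ds, 0), "min_sup")
  expect_error(enumerate_frequent(ds, 1.5), "min_sup")
})

test_that("enumeration matches the brute-force lattice on random datasets", {
  for (seed in c(21, 22, 23, 24, 25)) {
    ds <- random_small_dataset(seed, n_graphs = 5, max_v = 6, max_e = 8,
                               n_labels = 4)
    min_count <- ceiling(0.4 * ds$n)
    got <- enumerate_frequent(ds, min_count = min_count)
    want <- oracle_frequent_patterns(ds, min_count)
    expect_equal(length(got), length(want), info = paste("seed", seed))
    # canonical uniqueness: no two yielded patterns isomorphic
    keys <- vapply(got, function(p) iso_invariant_key(p$graph), character(1))
    for (k in unique(keys[duplicated(keys)])) {
      grp <- got[keys == k]
      for (a in seq_along(grp)) for (b in seq_len(a - 1L))
        expect_false(graphs_isomorphic(grp[[a]]$graph, grp[[b]]$graph))
    }
    # supports equal oracle supports, matched by isomorphism
    for (p in got) {
      hit <- Filter(function(w) graphs_isomorphic(w$graph, p$graph), want)
      expect_length(hit, 1L)
      expect_identical(p$support, hit[[1]]$support)
    }
  }
})

test_that("child supports are subsets of parents along the tree", {
  ds <- random_small_dataset(31, n_graphs = 6, max_v = 6, max_e = 7)
  stack_supports <- list()
  violations <- 0L
  gmsv:::gspan_walk(ds, min_count = 2L, visit = function(pattern, node) {
    depth <- node$depth + 1L
    stack_supports[[depth]] <<- pattern$support
    if (depth > 1L) {
      parent <- stack_supports[[depth - 1L]]
      if (!all(pattern$support %in% parent)) violations <<- violations + 1L
    }
    FALSE
  })
  expect_identical(violations, 0L)
})
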