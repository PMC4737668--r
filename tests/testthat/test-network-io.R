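write_matrix_csv <- function(w, path, header = TRUE) {
  colnames(w) <- sprintf("r%d", seq_len(ncol(w)))
  utils::write.csv(as.data.frame(w), path, row.names = FALSE)
  path
}

test_that("connectivity matrices are parsed, named and symmetrized", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  w <- rbind(c(0, 0.5, 0.2), c(0.5, 0, 0.8), c(0.2, 0.8, 0))
  write_matrix_csv(w, tmp)
  cm <- read_connectivity_matrix(tmp)
  expect_s3_class(cm, "connectivity_matrix")
  expect_length(cm$region_names, 3L)
  expect_equal(unname(cm$weights), w)

  # non-square block errors
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5,6"), bad)
  expect_error(read_connectivity_matrix(bad), "not square")

  # asymmetric entries are averaged with a warning
  asym <- withr::local_tempfile(fileext = ".csv")
  wa <- rbind(c(0, 0.8), c(0.6, 0))
  write_matrix_csv(wa, asym)
  expect_warning(cma <- read_connectivity_matrix(asym), "symmetrized")
  expect_equal(cma$weights[1, 2], 0.7)
  expect_equal(cma$weights[2, 1], 0.7)
})

test_that("link-weight normalization rescales off-diagonal range", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  w <- rbind(c(0, 2, 4), c(2, 0, 10), c(4, 10, 0))
  write_matrix_csv(w, tmp)
  cm <- normalize_link_weights(read_connectivity_matrix(tmp))
  expect_equal(cm$weights[1, 2], 0)
  expect_equal(cm$weights[1, 3], 0.25)
  expect_equal(cm$weights[2, 3], 1)
  wconst <- rbind(c(0, 1), c(1, 0))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(wconst, tmp2)
  expect_error(normalize_link_weights(read_connectivity_matrix(tmp2)),
               "constant")
})

test_that("thresholding uses strict > by default and is monotone", {
  w <- rbind(c(0, 0.95, 0.9, -0.99),
             c(0.95, 0, 0.91, 0.2),
             c(0.9, 0.91, 0, 0.92),
             c(-0.99, 0.2, 0.92, 0))
  cm <- structure(list(weights = w, region_names = as.character(1:4),
                       subject_id = "s"), class = "connectivity_matrix")
  g <- threshold_to_graph(cm, 0.9)
  # strictly above 0.9: (1,2), (2,3), (3,4); the 0.9 tie and the negative
  # weight are excluded
  expect_equal(nrow(g$edges), 3L)
  expect_false(any(g$edges[, 1] == 1 & g$edges[, 2] == 3))
  g_ge <- threshold_to_graph(cm, 0.9, strict = FALSE)
  expect_equal(nrow(g_ge$edges), 4L)
  expect_equal(length(g$vlabels), 4L)  # isolated vertices retained
  # raising the threshold never adds edges
  for (th in c(0, 0.5, 0.91, 0.94, 1)) {
    lo <- threshold_to_graph(cm, th)
    hi <- threshold_to_graph(cm, th + 0.02)
    expect_lte(nrow(hi$edges), nrow(lo$edges))
  }
  # negative weights never become edges, whatever the threshold
  gneg <- threshold_to_graph(cm, -2)
  expect_false(any(gneg$edges[, 1] == 1 & gneg$edges[, 2] == 4))
})

test_that("the committed fixture round-trips through the readers", {
  dir <- system.file("extdata", "fixture6", package = "gmsv")
  ds <- read_brain_dataset(file.path(dir, "manifest.csv"), threshold = 0.5)
  expect_equal(ds$n, 6L)
  expect_equal(ds$labels, c(1, 1, 1, -1, -1, -1))
  sv <- read_side_view_csv(file.path(dir, "view1.csv"), ds$ids)
  expect_equal(nrow(sv$features), 6L)
  expect_equal(ncol(sv$features), 3L)
  labels <- read_labels_csv(file.path(dir, "labels.csv"), ds$ids)
  expect_equal(labels, ds$labels)
  # regenerate the same simulation: graphs must be isomorphic pairwise
  cfg <- simulation_config(n_pos = 3, n_neg = 3, n_nodes = 10,
                           edge_density = 0.15, seed = 20,
                           views = list(list(d = 3, class_mean_gap = 3,
                                             noise_sd = 1)))
  sim <- generate_dataset(cfg)
  for (i in 1:6)
    expect_true(graphs_isomorphic(ds$graphs[[i]], sim$dataset$graphs[[i]]))
  expect_equal(unname(sv$features), unname(sim$views[[1]]$features),
               tolerance = 1e-12)
})

test_that("mining results export to JSON with region edge lists", {
  dir <- system.file("extdata", "fixture6", package = "gmsv")
  ds <- read_brain_dataset(file.path(dir, "manifest.csv"), threshold = 0.5)
  sv <- read_side_view_csv(file.path(dir, "view1.csv"), ds$ids)
  res <- mine_top_k(ds, list(sv), k = 3, min_sup = 0.5)
  out <- withr::local_tempfile(fileext = ".json")
  write_mining_result_json(res, out, ids = ds$ids)
  parsed <- jsonlite::read_json(out)
  expect_length(parsed$patterns, 3L)
  expect_true(all(c("gside", "support", "vertices") %in%
                  names(parsed$patterns[[1]])))
  expect_equal(parsed$config$k, 3L)
})
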