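# Seeded generator for synthetic brain-network datasets: per-subject random
# background graphs on a fixed region vocabulary, a planted subgraph pattern
# enriched in one class, and side views whose features carry a controllable
# class-mean separation — the regime in which side-information consistency
# holds by construction.

#' Simulation configuration
#'
#' Defaults emulate a small neuroimaging case-control study: a few dozen
#' subjects, 90 atlas regions per graph, sparse background connectivity, a
#' 3-edge planted pattern strongly enriched in the positive class, and one
#' side view whose class means are separated by 3 within-class standard
#' deviations (strong but realistic consistency; a gap of 0 gives an
#' uninformative view for null calibration).
#'
#' @param n_pos,n_neg positive / negative subject counts.
#' @param n_nodes number of region labels per graph (default 90).
#' @param edge_density background edge probability in \code{(0, 1)}.
#' @param planted_pattern a \code{\link{labeled_graph}} whose vertex labels
#'   index regions in \code{1..n_nodes}; default a 3-edge path over regions
#'   1-2-3-4.
#' @param p_present_pos,p_present_neg probability the planted pattern's edges
#'   are forced present in a positive / negative subject.
#' @param views list of view specs, each a list with \code{d} (measure
#'   count), \code{class_mean_gap} (distance between class means in units of
#'   \code{noise_sd}), \code{noise_sd}, and optionally \code{weight}.
#' @param seed integer seed.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_pos = 20, n_neg = 20, n_nodes = 90,
                              edge_density = 0.05,
                              planted_pattern = NULL,
                              p_present_pos = 0.9, p_present_neg = 0.1,
                              views = list(list(d = 10, class_mean_gap = 3,
                                                noise_sd = 1)),
                              seed = 1) {
  if (is.null(planted_pattern))
    planted_pattern <- labeled_graph(1:4, cbind(1:3, 2:4))
  if (n_pos + n_neg < 2) stop("need at least two subjects")
  if (edge_density <= 0 || edge_density >= 1)
    stop("edge_density must lie in (0, 1)")
  for (p in c(p_present_pos, p_present_neg))
    if (p < 0 || p > 1) stop("presence probabilities must lie in [0, 1]")
  if (any(planted_pattern$vlabels < 1L | planted_pattern$vlabels > n_nodes))
    stop("planted pattern uses labels outside the node vocabulary")
  if (anyDuplicated(planted_pattern$vlabels))
    stop("planted pattern labels must be distinct (region semantics)")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_nodes = as.integer(n_nodes),
                 edge_density = edge_density,
                 planted_pattern = planted_pattern,
                 p_present_pos = p_present_pos,
                 p_present_neg = p_present_neg,
                 views = views, seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic dataset with planted structure
#'
#' Per subject, a background Erdos-Renyi graph is drawn on the region
#' vocabulary (each region appears exactly once per graph, so planted-pattern
#' support is unambiguous); with class-conditional probability the planted
#' pattern's edges are then forced present (OR-ed into the background). Each
#' side view draws features from a class-dependent mean — the positive-class
#' mean is offset by \code{class_mean_gap * noise_sd} in Euclidean norm —
#' plus isotropic Gaussian noise. Identical seeds give identical output.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{dataset} (a \code{\link{graph_dataset}}; positives
#'   first, labels +1/-1), \code{views} (list of \code{\link{side_view}}),
#'   and \code{truth} (planted pattern, per-subject planting indicator, and
#'   the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    m <- config$n_nodes
    labels <- c(rep(1, config$n_pos), rep(-1, config$n_neg))
    p_present <- ifelse(labels > 0, config$p_present_pos,
                        config$p_present_neg)
    planted <- stats::runif(n) < p_present
    ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    pat <- config$planted_pattern
    pat_edges <- cbind(pat$vlabels[pat$edges[, 1L]],
                       pat$vlabels[pat$edges[, 2L]])
    graphs <- vector("list", n)
    for (s in seq_len(n)) {
      keep <- stats::runif(nrow(ut)) < config$edge_density
      edges <- ut[keep, , drop = FALSE]
      if (planted[s] && nrow(pat_edges) > 0L) {
        edges <- rbind(edges, pat_edges)
        key <- paste(pmin(edges[, 1L], edges[, 2L]),
                     pmax(edges[, 1L], edges[, 2L]))
        edges <- edges[!duplicated(key), , drop = FALSE]
      }
      graphs[[s]] <- labeled_graph(seq_len(m),
                                   if (nrow(edges) > 0L) edges else NULL)
    }
    ids <- sprintf("s%03d", seq_len(n))
    dataset <- graph_dataset(graphs, labels = labels, ids = ids)
    views <- lapply(seq_along(config$views), function(vi) {
      vs <- config$views[[vi]]
      d <- vs$d
      sd <- if (is.null(vs$noise_sd)) 1 else vs$noise_sd
      gap <- if (is.null(vs$class_mean_gap)) 0 else vs$class_mean_gap
      wt <- if (is.null(vs$weight)) 1 else vs$weight
      shift <- gap * sd / sqrt(d)
      feats <- matrix(stats::rnorm(n * d, sd = sd), n, d)
      feats[labels > 0, ] <- feats[labels > 0, ] + shift
      colnames(feats) <- sprintf("m%02d", seq_len(d))
      rownames(feats) <- ids
      side_view(feats, weight = wt, name = sprintf("view%d", vi))
    })
    list(dataset = dataset, views = views,
         truth = list(planted_pattern = pat, planted = planted,
                      config = config))
  })
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits one connectivity CSV per subject (weight 1.0 for present edges, 0.0
#' otherwise, so any threshold in \code{(0, 1)} reproduces the graphs), one
#' CSV per side view, a labels CSV and a manifest CSV — the full input
#' surface of the package's readers. Writing is deterministic: the same
#' simulation writes byte-identical files.
#'
#' @param sim output of \code{\link{generate_dataset}}.
#' @param dir target directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- sim$dataset
  m <- n_vertices(dataset$graphs[[1L]])
  region <- sprintf("r%02d", seq_len(m))
  paths <- character(dataset$n)
  for (s in seq_len(dataset$n)) {
    g <- dataset$graphs[[s]]
    w <- matrix(0, m, m, dimnames = list(region, region))
    if (n_edges(g) > 0L) {
      w[g$edges] <- 1
      w[g$edges[, c(2L, 1L)]] <- 1
    }
    paths[s] <- paste0(dataset$ids[s], ".csv")
    utils::write.csv(w, file.path(dir, paths[s]), row.names = FALSE)
  }
  for (v in sim$views) {
    df <- data.frame(subject_id = dataset$ids, v$features,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(v$name, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(subject_id = dataset$ids,
                              label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(subject_id = dataset$ids, path = paths,
                              label = dataset$labels),
                   manifest, row.names = FALSE)
  invisible(manifest)
}
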