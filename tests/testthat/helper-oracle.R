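# Brute-force oracles, independent of the gSpan enumeration path: lattice
# enumeration of all connected subgraphs, exhaustive injective-map
# isomorphism checks, dense quadratic-form scoring, and small random dataset
# generators.

# every injective label-preserving map, by explicit enumeration over all
# ordered vertex subsets of the host (small graphs only)
exhaustive_monomorphism <- function(pattern, host) {
  np <- length(pattern$vlabels)
  nh <- length(host$vlabels)
  if (np > nh) return(FALSE)
  perms <- function(v, k) {
    if (k == 0L) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1L))
        out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (map in perms(seq_len(nh), np)) {
    if (any(host$vlabels[map] != pattern$vlabels)) next
    ok <- TRUE
    for (e in seq_len(nrow(pattern$edges))) {
      if (nrow(pattern$edges) == 0L) break
      a <- map[pattern$edges[e, 1L]]; b <- map[pattern$edges[e, 2L]]
      el <- gmsv:::edge_label(host, a, b)
      if (is.na(el) || el != pattern$elabels[e]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

graphs_isomorphic <- function(g1, g2) {
  if (length(g1$vlabels) != length(g2$vlabels)) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$vlabels), sort(g2$vlabels))) return(FALSE)
  is_subgraph_isomorphic(g1, g2) && is_subgraph_isomorphic(g2, g1)
}

# all connected subgraphs of g: single vertices plus every connected edge
# subset (vertices = covered endpoints)
connected_subgraphs_of <- function(g) {
  out <- lapply(g$vlabels, labeled_graph)
  ne <- nrow(g$edges)
  if (ne == 0L) return(out)
  for (mask in seq_len(2L^ne - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
    verts <- sort(unique(as.vector(g$edges[sel, , drop = FALSE])))
    remap <- match(seq_len(length(g$vlabels)), verts)
    sub <- labeled_graph(g$vlabels[verts],
                         cbind(remap[g$edges[sel, 1L]],
                               remap[g$edges[sel, 2L]]),
                         g$elabels[sel])
    if (gmsv:::graph_is_connected(sub)) out[[length(out) + 1L]] <- sub
  }
  out
}

# invariant key for cheap grouping before pairwise isomorphism checks
iso_invariant_key <- function(g) {
  degl <- sort(paste(g$vlabels, vapply(g$adj, length, integer(1))))
  el <- if (nrow(g$edges) > 0L)
    sort(paste(pmin(g$vlabels[g$edges[, 1L]], g$vlabels[g$edges[, 2L]]),
               g$elabels,
               pmax(g$vlabels[g$edges[, 1L]], g$vlabels[g$edges[, 2L]])))
  else character(0)
  paste(length(g$vlabels), nrow(g$edges),
        paste(degl, collapse = "|"), paste(el, collapse = "|"))
}

# brute-force lattice oracle: all frequent connected patterns with
# oracle-computed supports, deduplicated by isomorphism
oracle_frequent_patterns <- function(dataset, min_count, max_edges = Inf) {
  buckets <- list()
  for (g in dataset$graphs) {
    for (sub in connected_subgraphs_of(g)) {
      if (nrow(sub$edges) > max_edges) next
      key <- iso_invariant_key(sub)
      known <- buckets[[key]]
      dup <- FALSE
      if (!is.null(known)) {
        for (k in known) if (graphs_isomorphic(k, sub)) { dup <- TRUE; break }
      }
      if (!dup) buckets[[key]] <- c(known, list(sub))
    }
  }
  reps <- unlist(buckets, recursive = FALSE)
  pats <- lapply(reps, compute_support, dataset = dataset)
  pats[vapply(pats, function(p) length(p$support) >= min_count, logical(1))]
}

dense_gside <- function(pattern, lap, which = "L") {
  f <- as.numeric(pattern$indicator)
  as.numeric(t(f) %*% lap[[which]] %*% f)
}

# oracle top-k: dense scoring, ascending; returns the comparison signature
# (sorted scores + sorted support keys) for the k best
selection_signature <- function(scores, supports, k = length(scores)) {
  ord <- order(scores)
  keep <- ord[seq_len(min(k, length(ord)))]
  list(scores = unname(sort(scores[keep])),
       supports = unname(sort(vapply(supports[keep], function(s)
         paste(s, collapse = ","), character(1)))))
}

result_signature <- function(result) {
  selection_signature(result$scores,
                      lapply(result$patterns, `[[`, "support"))
}

# random small graph dataset with repeated labels allowed
random_small_dataset <- function(seed, n_graphs = 5, max_v = 6, max_e = 8,
                                 n_labels = 4, labeled = TRUE) {
  withr::with_seed(seed, {
    graphs <- lapply(seq_len(n_graphs), function(i) {
      nv <- sample(3:max_v, 1)
      vlab <- sample.int(n_labels, nv, replace = TRUE)
      pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
      ne <- min(sample.int(max_e, 1), nrow(pairs))
      sel <- sample.int(nrow(pairs), ne)
      labeled_graph(vlab, pairs[sel, , drop = FALSE])
    })
    labels <- if (labeled)
      sample(c(rep(1, ceiling(n_graphs / 2)),
               rep(-1, floor(n_graphs / 2))))
    else rep(NA_real_, n_graphs)
    graph_dataset(graphs, labels = labels)
  })
}

random_views <- function(seed, n, d = 3, gap = 1, labels = NULL) {
  withr::with_seed(seed, {
    feats <- matrix(rnorm(n * d), n, d)
    if (!is.null(labels) && gap != 0)
      feats[labels > 0, ] <- feats[labels > 0, ] + gap / sqrt(d)
    list(side_view(feats))
  })
}
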