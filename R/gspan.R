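# gSpan-style canonical enumeration of connected subgraph patterns.
#
# A DFS code is an integer matrix with columns (i, j, li, le, lj): i and j are
# 0-based DFS discovery indices, li/lj vertex labels, le the edge label. The
# first tuple has (i, j) = (0, 1); each later tuple is either a forward edge
# (j = max index so far + 1, grown from a vertex on the rightmost path) or a
# backward edge (from the rightmost vertex to an earlier rightmost-path
# vertex). A pattern is identified by its lexicographically minimum DFS code;
# enumeration skips non-minimal codes, so each isomorphism class is visited
# exactly once.

dfs_code_matrix <- function(rows) {
  m <- matrix(as.integer(rows), ncol = 5L, byrow = FALSE)
  colnames(m) <- c("i", "j", "li", "le", "lj")
  m
}

empty_dfs_code <- function() {
  dfs_code_matrix(matrix(integer(0), ncol = 5L))
}

# -1 / 0 / 1 comparison of two DFS edge tuples under gSpan's neighborhood
# order: backward before forward; among backwards, smaller target first;
# among forwards, deeper source first; ties broken on (li, le, lj).
cmp_dfs_edge <- function(a, b) {
  fa <- a[1L] < a[2L]
  fb <- b[1L] < b[2L]
  if (fa && fb) {
    if (a[2L] != b[2L]) return(if (a[2L] < b[2L]) -1L else 1L)
    if (a[1L] != b[1L]) return(if (a[1L] > b[1L]) -1L else 1L)
  } else if (!fa && !fb) {
    if (a[1L] != b[1L]) return(if (a[1L] < b[1L]) -1L else 1L)
    if (a[2L] != b[2L]) return(if (a[2L] < b[2L]) -1L else 1L)
  } else if (!fa && fb) {
    return(if (a[1L] < b[2L]) -1L else 1L)
  } else {
    return(if (b[1L] < a[2L]) 1L else -1L)
  }
  for (k in 3L:5L) {
    if (a[k] != b[k]) return(if (a[k] < b[k]) -1L else 1L)
  }
  0L
}

# lexicographic comparison of two DFS codes; a proper prefix is smaller
cmp_dfs_code <- function(c1, c2) {
  m <- min(nrow(c1), nrow(c2))
  for (t in seq_len(m)) {
    cc <- cmp_dfs_edge(c1[t, ], c2[t, ])
    if (cc != 0L) return(cc)
  }
  if (nrow(c1) == nrow(c2)) 0L
  else if (nrow(c1) < nrow(c2)) -1L else 1L
}

code_key <- function(code, root_label = NULL) {
  if (is.null(code) || nrow(code) == 0L)
    return(paste0("v", root_label))
  paste(apply(code, 1L, paste, collapse = ","), collapse = ";")
}

#' Reconstruct the pattern graph encoded by a DFS code
#'
#' @param code DFS code matrix with columns \code{(i, j, li, le, lj)}
#'   (0-based vertex indices).
#' @param root_label vertex label for the single-vertex pattern when
#'   \code{code} has no rows.
#' @return a \code{\link{labeled_graph}} whose vertex order is DFS discovery
#'   order.
#' @export
graph_from_dfs_code <- function(code, root_label = NULL) {
  if (is.null(code) || nrow(code) == 0L) {
    if (is.null(root_label)) stop("empty code needs a root label")
    return(labeled_graph(root_label))
  }
  if (ncol(code) != 5L) stop("malformed DFS code: expected 5 columns")
  nv <- max(code[, 1L:2L]) + 1L
  vlab <- rep(NA_integer_, nv)
  for (t in seq_len(nrow(code))) {
    vlab[code[t, 1L] + 1L] <- code[t, 3L]
    vlab[code[t, 2L] + 1L] <- code[t, 5L]
  }
  if (anyNA(vlab)) stop("malformed DFS code: undetermined vertex label")
  labeled_graph(vlab, cbind(code[, 1L] + 1L, code[, 2L] + 1L), code[, 4L])
}

# internal pattern bookkeeping for the walker: vertex labels in discovery
# order, 1-based rightmost path, and an adjacency indicator
pattern_state <- function(code, root_label = NULL) {
  if (is.null(code) || nrow(code) == 0L) {
    return(list(code = empty_dfs_code(), root_label = root_label,
                vlabels = as.integer(root_label),
                rmpath = 1L,
                has_edge = matrix(FALSE, 1L, 1L)))
  }
  nv <- max(code[, 1L:2L]) + 1L
  vlab <- rep(NA_integer_, nv)
  has_edge <- matrix(FALSE, nv, nv)
  parent <- rep(NA_integer_, nv)
  for (t in seq_len(nrow(code))) {
    a <- code[t, 1L] + 1L; b <- code[t, 2L] + 1L
    vlab[a] <- code[t, 3L]; vlab[b] <- code[t, 5L]
    has_edge[a, b] <- TRUE; has_edge[b, a] <- TRUE
    if (code[t, 1L] < code[t, 2L]) parent[b] <- a  # forward edge
  }
  rmpath <- nv
  while (rmpath[1L] != 1L) rmpath <- c(parent[rmpath[1L]], rmpath)
  list(code = code, root_label = NULL, vlabels = vlab, rmpath = rmpath,
       has_edge = has_edge)
}

# All rightmost-path one-edge extensions of `state` realized by embedding
# `map` (1-based host vertex per pattern vertex) in `host`. Returns a list of
# list(tuple = c(i,j,li,le,lj), map = new map).
embedding_extensions <- function(state, map, host) {
  out <- list()
  nv <- length(state$vlabels)
  rm_v <- nv  # rightmost vertex (last discovered)
  rmpath <- state$rmpath
  # backward: rightmost vertex -> earlier rightmost-path vertex
  if (length(rmpath) > 2L) {
    for (v in rmpath[seq_len(length(rmpath) - 2L)]) {
      if (state$has_edge[rm_v, v]) next
      el <- edge_label(host, map[rm_v], map[v])
      if (is.na(el)) next
      out[[length(out) + 1L]] <- list(
        tuple = c(rm_v - 1L, v - 1L, state$vlabels[rm_v], el,
                  state$vlabels[v]),
        map = map)
    }
  }
  # forward: from each rightmost-path vertex to a fresh host vertex
  for (v in rev(rmpath)) {
    hv <- map[v]
    for (w in host$adj[[hv]]) {
      if (w %in% map) next
      el <- edge_label(host, hv, w)
      out[[length(out) + 1L]] <- list(
        tuple = c(v - 1L, nv, state$vlabels[v], el, host$vlabels[w]),
        map = c(map, w))
    }
  }
  out
}

# group candidate extensions over all embeddings of all supporting graphs;
# returns a list keyed by tuple with fields tuple, support, maps (per graph)
collect_extensions <- function(state, embeddings, dataset) {
  cands <- new.env(parent = emptyenv())
  for (gid_chr in names(embeddings)) {
    gid <- as.integer(gid_chr)
    host <- dataset$graphs[[gid]]
    maps <- embeddings[[gid_chr]]
    seen_tuples_maps <- list()
    for (r in seq_len(nrow(maps))) {
      exts <- embedding_extensions(state, maps[r, ], host)
      for (e in exts) {
        key <- paste(e$tuple, collapse = ",")
        entry <- if (exists(key, envir = cands, inherits = FALSE))
          get(key, envir = cands) else list(tuple = e$tuple, maps = list())
        gmaps <- entry$maps[[gid_chr]]
        entry$maps[[gid_chr]] <- rbind(gmaps, e$map)
        assign(key, entry, envir = cands)
      }
    }
  }
  out <- as.list(cands)
  # drop duplicate embeddings (same map can arise from distinct parents)
  for (k in seq_along(out)) {
    out[[k]]$maps <- lapply(out[[k]]$maps, function(m) unique(m))
    out[[k]]$support <- length(out[[k]]$maps)
  }
  out
}

#' Test whether a DFS code is the minimum (canonical) code of its graph
#'
#' Greedily rebuilds the minimum DFS code of the graph that \code{code}
#' encodes — at every step taking the smallest rightmost-path extension over
#' all embeddings of the current minimal prefix into the graph itself — and
#' compares it prefix-wise against \code{code}.
#'
#' @param code DFS code matrix (at least one edge row).
#' @return \code{TRUE} iff \code{code} is lexicographically minimal among all
#'   DFS codes of the graph it encodes.
#' @export
is_minimum_dfs_code <- function(code) {
  if (is.null(code) || nrow(code) == 0L)
    stop("malformed DFS code: no edges")
  if (ncol(code) != 5L) stop("malformed DFS code: expected 5 columns")
  g <- graph_from_dfs_code(code)
  # minimal first tuple over both orientations of every edge
  best <- NULL
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1L]; b <- g$edges[e, 2L]; el <- g$elabels[e]
    for (t in list(c(0L, 1L, g$vlabels[a], el, g$vlabels[b]),
                   c(0L, 1L, g$vlabels[b], el, g$vlabels[a]))) {
      if (is.null(best) || cmp_dfs_edge(t, best) < 0L) best <- t
    }
  }
  if (cmp_dfs_edge(code[1L, ], best) != 0L) return(FALSE)
  # embeddings of the minimal prefix into g itself
  maps <- list()
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1L]; b <- g$edges[e, 2L]; el <- g$elabels[e]
    if (el == best[4L]) {
      if (g$vlabels[a] == best[3L] && g$vlabels[b] == best[5L])
        maps[[length(maps) + 1L]] <- c(a, b)
      if (g$vlabels[b] == best[3L] && g$vlabels[a] == best[5L])
        maps[[length(maps) + 1L]] <- c(b, a)
    }
  }
  min_code <- dfs_code_matrix(matrix(best, nrow = 1L))
  for (t in 2L:nrow(code)) {
    if (t > nrow(code)) break
    state <- pattern_state(min_code)
    ext_best <- NULL
    ext_maps <- list()
    for (map in maps) {
      for (e in embedding_extensions(state, map, g)) {
        cc <- if (is.null(ext_best)) -1L else cmp_dfs_edge(e$tuple, ext_best)
        if (cc < 0L) {
          ext_best <- e$tuple
          ext_maps <- list(e$map)
        } else if (cc == 0L) {
          ext_maps[[length(ext_maps) + 1L]] <- e$map
        }
      }
    }
    if (cmp_dfs_edge(code[t, ], ext_best) != 0L) return(FALSE)
    min_code <- rbind(min_code, ext_best)
    maps <- unique(ext_maps)
  }
  TRUE
}

#' Rightmost-path extensions of a pattern over a dataset
#'
#' Generates every one-edge extension of \code{code} (backward from the
#' rightmost vertex, forward from the rightmost path) realized by at least
#' one embedding in the dataset, together with the updated embedding lists.
#' Child support sets are always subsets of the parent's.
#'
#' @param code DFS code of the current pattern (may be empty for a
#'   single-vertex pattern when \code{root_label} is given).
#' @param embeddings named list (graph index as name) of embedding matrices,
#'   one row per embedding.
#' @param dataset a \code{\link{graph_dataset}}.
#' @param root_label label of the single-vertex pattern when \code{code} is
#'   empty.
#' @return list of candidates, each with \code{tuple}, \code{code} (extended
#'   code), \code{support} (count of supporting graphs) and \code{maps}
#'   (embedding lists), sorted in canonical extension order.
#' @export
rightmost_extensions <- function(code, embeddings, dataset, root_label = NULL) {
  state <- pattern_state(code, root_label)
  cands <- collect_extensions(state, embeddings, dataset)
  if (length(cands) == 0L) return(list())
  ord <- order_tuples(lapply(cands, `[[`, "tuple"))
  cands <- cands[ord]
  lapply(cands, function(cd) {
    list(tuple = cd$tuple,
         code = rbind(state$code, cd$tuple),
         support = cd$support,
         maps = cd$maps)
  })
}

# order indices of a list of tuples under cmp_dfs_edge (insertion sort; the
# candidate sets at one node are small)
order_tuples <- function(tuples) {
  n <- length(tuples)
  idx <- seq_len(n)
  for (a in seq_len(n - 1L)) {
    if (n < 2L) break
    best <- a
    for (b in (a + 1L):n) {
      if (cmp_dfs_edge(tuples[[idx[b]]], tuples[[idx[best]]]) < 0L) best <- b
    }
    if (best != a) idx[c(a, best)] <- idx[c(best, a)]
  }
  idx
}

# Depth-first walk of the canonical DFS-code tree over frequent patterns.
# visit(pattern, node) is called on every frequent, canonical pattern in
# canonical depth-first order and must return TRUE to prune the subtree below
# the pattern. node carries code, root_label, depth. Counters for frequency /
# canonicality skips are accumulated into the returned list.
gspan_walk <- function(dataset, min_count, visit, max_edges = Inf,
                       include_singletons = TRUE) {
  n <- dataset$n
  counters <- list(visited = 0L, pruned_bound = 0L,
                   skipped_infrequent = 0L, skipped_noncanonical = 0L)
  recurse <- function(code, root_label, embeddings, depth) {
    support <- as.integer(names(embeddings))
    patt_graph <- graph_from_dfs_code(code, root_label)
    pattern <- new_subgraph_pattern(patt_graph, support, n,
                                    code = if (nrow(code) > 0L) code else NULL)
    is_singleton <- nrow(code) == 0L
    prune <- FALSE
    if (!is_singleton || include_singletons) {
      counters$visited <<- counters$visited + 1L
      prune <- isTRUE(visit(pattern,
                            list(code = code, root_label = root_label,
                                 depth = depth)))
      if (prune) counters$pruned_bound <<- counters$pruned_bound + 1L
    }
    if (prune || nrow(code) >= max_edges) return(invisible(NULL))
    cands <- rightmost_extensions(code, embeddings, dataset, root_label)
    for (cd in cands) {
      if (cd$support < min_count) {
        counters$skipped_infrequent <<- counters$skipped_infrequent + 1L
        next
      }
      if (!is_minimum_dfs_code(cd$code)) {
        counters$skipped_noncanonical <<- counters$skipped_noncanonical + 1L
        next
      }
      recurse(cd$code, NULL, cd$maps, depth + 1L)
    }
    invisible(NULL)
  }
  # roots: frequent vertex labels in ascending order
  all_labels <- sort(unique(unlist(lapply(dataset$graphs, `[[`, "vlabels"))))
  for (lab in all_labels) {
    embeddings <- list()
    for (gid in seq_len(n)) {
      hits <- which(dataset$graphs[[gid]]$vlabels == lab)
      if (length(hits) > 0L)
        embeddings[[as.character(gid)]] <- matrix(hits, ncol = 1L)
    }
    if (length(embeddings) < min_count) {
      counters$skipped_infrequent <- counters$skipped_infrequent + 1L
      next
    }
    recurse(empty_dfs_code(), lab, embeddings, 0L)
  }
  counters
}

#' Enumerate frequent connected subgraph patterns
#'
#' Canonical gSpan enumeration: yields one pattern per isomorphism class
#' (identified by its minimum DFS code) whose support reaches the frequency
#' threshold, in depth-first canonical order. Infrequent nodes prune their
#' whole subtree by anti-monotonicity.
#'
#' @param dataset a \code{\link{graph_dataset}}.
#' @param min_sup minimum support as a fraction of the dataset size, in
#'   \code{(0, 1]}; the count threshold is \code{ceiling(min_sup * n)}.
#' @param max_edges cap on pattern edge count (default unbounded).
#' @param min_count absolute count threshold overriding \code{min_sup} when
#'   supplied.
#' @param include_singletons include single-vertex patterns (default TRUE).
#' @return list of \code{subgraph_pattern} objects.
#' @export
enumerate_frequent <- function(dataset, min_sup, max_edges = Inf,
                               min_count = NULL, include_singletons = TRUE) {
  stopifnot(inherits(dataset, "graph_dataset"))
  if (is.null(min_count)) {
    if (!is.numeric(min_sup) || min_sup <= 0 || min_sup > 1)
      stop("min_sup must lie in (0, 1]")
    min_count <- as.integer(ceiling(min_sup * dataset$n))
  }
  min_count <- max(1L, as.integer(min_count))
  acc <- list()
  gspan_walk(dataset, min_count,
             visit = function(pattern, node) {
               acc[[length(acc) + 1L]] <<- pattern
               FALSE
             },
             max_edges = max_edges,
             include_singletons = include_singletons)
  acc
}
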