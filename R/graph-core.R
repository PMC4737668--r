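#' Construct a labeled graph
#'
#' An undirected simple graph with integer vertex labels and optional integer
#' edge labels. Vertex IDs are local indices \code{1..n_vertices}; only labels
#' matter for isomorphism. For brain networks the vertex label is the atlas
#' region index, so each label occurs at most once per graph, but repeated
#' labels are fully supported.
#'
#' @param vlabels integer vector of vertex labels; vertex \code{i} has label
#'   \code{vlabels[i]}.
#' @param edges two-column integer matrix of vertex-index pairs (unordered),
#'   or \code{NULL} for an edgeless graph.
#' @param elabels integer vector of edge labels aligned with the rows of
#'   \code{edges}; defaults to the single label \code{0} throughout.
#' @return an object of class \code{labeled_graph} with components
#'   \code{vlabels}, \code{edges} (rows sorted with smaller index first),
#'   \code{elabels} and \code{adj} (neighbor index lists).
#' @export
labeled_graph <- function(vlabels, edges = NULL, elabels = NULL) {
  vlabels <- as.integer(vlabels)
  nv <- length(vlabels)
  if (nv < 1L) stop("a labeled graph needs at least one vertex")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
    elabels <- integer(0)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (is.null(elabels)) elabels <- rep(0L, nrow(edges))
    elabels <- as.integer(elabels)
    if (length(elabels) != nrow(edges))
      stop("elabels must have one entry per edge")
    if (any(edges < 1L) || any(edges > nv))
      stop("edge endpoint refers to an undeclared vertex")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, c(2L, 1L)]
    key <- paste(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key)) stop("parallel edges are not allowed")
  }
  adj <- vector("list", nv)
  for (v in seq_len(nv)) adj[[v]] <- integer(0)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  structure(list(vlabels = vlabels, edges = edges, elabels = elabels,
                 adj = adj),
            class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph: %d vertices, %d edges>\n",
              length(x$vlabels), nrow(x$edges)))
  invisible(x)
}

n_vertices <- function(g) length(g$vlabels)
n_edges <- function(g) nrow(g$edges)

# label of edge (a, b), or NA when absent
edge_label <- function(g, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  hit <- which(g$edges[, 1L] == a & g$edges[, 2L] == b)
  if (length(hit) == 0L) return(NA_integer_)
  g$elabels[hit[1L]]
}

graph_is_connected <- function(g) {
  nv <- n_vertices(g)
  if (nv == 1L) return(TRUE)
  seen <- logical(nv)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in g$adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

#' Assemble a dataset of labeled graphs
#'
#' @param graphs list of \code{\link{labeled_graph}} objects.
#' @param labels numeric vector in \code{{-1, +1}} (or \code{NA} for
#'   unlabeled), aligned with \code{graphs}; may be \code{NULL} when no
#'   supervision is available.
#' @param ids character vector of unique subject identifiers; defaults to
#'   \code{"g1".."gn"}.
#' @return object of class \code{graph_dataset}.
#' @export
graph_dataset <- function(graphs, labels = NULL, ids = NULL) {
  if (length(graphs) < 1L) stop("dataset must contain at least one graph")
  if (!all(vapply(graphs, inherits, logical(1), "labeled_graph")))
    stop("all elements of graphs must be labeled_graph objects")
  n <- length(graphs)
  if (is.null(labels)) labels <- rep(NA_real_, n)
  labels <- as.numeric(labels)
  if (length(labels) != n) stop("labels must align with graphs")
  bad <- !is.na(labels) & !(labels %in% c(-1, 1))
  if (any(bad)) stop("labels must be -1, +1 or NA")
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids))
    stop("ids must be unique and align with graphs")
  structure(list(graphs = graphs, labels = labels, ids = ids, n = n),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  nl <- sum(!is.na(x$labels))
  cat(sprintf("<graph_dataset: %d graphs (%d labeled: %d positive, %d negative)>\n",
              x$n, nl, sum(x$labels == 1, na.rm = TRUE),
              sum(x$labels == -1, na.rm = TRUE)))
  invisible(x)
}

#' Label-preserving subgraph isomorphism test
#'
#' Decides whether \code{pattern} occurs in \code{host}: whether there is an
#' injective vertex map preserving vertex labels under which every pattern
#' edge (with its label) maps onto a host edge. This is subgraph monomorphism,
#' not induced-subgraph isomorphism: extra host edges among mapped vertices
#' are allowed. Implemented as label-filtered backtracking; intended for small
#' patterns and hosts (it is the reference oracle — the miner counts support
#' incrementally through embedding lists instead).
#'
#' @param pattern,host \code{\link{labeled_graph}} objects.
#' @param all_embeddings if \code{TRUE}, return the matrix of all injective
#'   maps (one row per embedding, column \code{i} = host vertex for pattern
#'   vertex \code{i}) instead of a logical.
#' @return logical, or an embedding matrix when \code{all_embeddings = TRUE}.
#' @export
is_subgraph_isomorphic <- function(pattern, host, all_embeddings = FALSE) {
  stopifnot(inherits(pattern, "labeled_graph"), inherits(host, "labeled_graph"))
  np <- n_vertices(pattern)
  if (np == 0L) stop("pattern must have at least one vertex")
  nh <- n_vertices(host)
  found <- list()
  # order pattern vertices so each (after the first) touches an earlier one
  # when the pattern is connected; fall back to declaration order otherwise
  ord <- seq_len(np)
  assign_map <- integer(np)
  used <- logical(nh)
  recurse <- function(pos) {
    if (pos > np) {
      if (all_embeddings) {
        found[[length(found) + 1L]] <<- assign_map
        return(FALSE)
      }
      return(TRUE)
    }
    pv <- ord[pos]
    # candidates: right label, unused, consistent with mapped neighbors
    for (hv in seq_len(nh)) {
      if (used[hv] || host$vlabels[hv] != pattern$vlabels[pv]) next
      ok <- TRUE
      for (pn in pattern$adj[[pv]]) {
        hm <- assign_map[pn]
        if (hm == 0L) next
        el <- edge_label(host, hv, hm)
        if (is.na(el) || el != edge_label(pattern, pv, pn)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_map[pv] <<- hv
      used[hv] <<- TRUE
      if (recurse(pos + 1L)) return(TRUE)
      assign_map[pv] <<- 0L
      used[hv] <<- FALSE
    }
    FALSE
  }
  hit <- recurse(1L)
  if (all_embeddings) {
    if (length(found) == 0L) return(matrix(integer(0), ncol = np))
    do.call(rbind, found)
  } else {
    hit
  }
}

#' Support set and indicator vector of a pattern
#'
#' Scans the dataset with the isomorphism oracle and records which graphs
#' contain the pattern. The indicator vector \code{f} has \code{f[j] = 1}
#' exactly when the pattern is a subgraph of graph \code{j}.
#'
#' @param pattern a \code{\link{labeled_graph}}.
#' @param dataset a \code{\link{graph_dataset}}.
#' @return object of class \code{subgraph_pattern} with components
#'   \code{graph}, \code{support} (sorted integer indices), \code{indicator}
#'   (binary vector of length \code{n}) and \code{code} (the minimum DFS code
#'   when constructed by the miner, otherwise \code{NULL}).
#' @export
compute_support <- function(pattern, dataset) {
  stopifnot(inherits(dataset, "graph_dataset"))
  hits <- which(vapply(dataset$graphs, function(g)
    is_subgraph_isomorphic(pattern, g), logical(1)))
  new_subgraph_pattern(pattern, hits, dataset$n, code = NULL)
}

new_subgraph_pattern <- function(graph, support, n, code = NULL) {
  support <- sort(as.integer(support))
  indicator <- integer(n)
  indicator[support] <- 1L
  structure(list(graph = graph, support = support, indicator = indicator,
                 code = code),
            class = "subgraph_pattern")
}

#' @export
print.subgraph_pattern <- function(x, ...) {
  cat(sprintf("<subgraph_pattern: %d vertices, %d edges, support %d/%d>\n",
              n_vertices(x$graph), n_edges(x$graph),
              length(x$support), length(x$indicator)))
  invisible(x)
}
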