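# Branch-and-bound top-k subgraph search guided by gSide.
#
# The miner walks the canonical gSpan DFS-code tree restricted to frequent,
# minimal codes. Each visited pattern is scored with gSide; a pattern enters
# the top-k container when it strictly improves on the current worst kept
# score (or the container is not yet full). After scoring, the subtree below
# the pattern is pruned when its lower bound qhat already reaches the
# threshold theta (the worst kept score): by the bound's supergraph
# guarantee, no descendant can then strictly beat theta, so pruned and
# unpruned runs keep identical patterns. theta starts at +Inf and pruning is
# inactive until the container fills.

# -1/0/1 order on pattern identities (minimum DFS code; single-vertex
# patterns order by label and precede any edge code)
cmp_pattern_identity <- function(code1, root1, code2, root2) {
  s1 <- is.null(code1) || nrow(code1) == 0L
  s2 <- is.null(code2) || nrow(code2) == 0L
  if (s1 && s2) {
    if (root1 == root2) return(0L)
    return(if (root1 < root2) -1L else 1L)
  }
  if (s1) return(-1L)
  if (s2) return(1L)
  cmp_dfs_code(code1, code2)
}

#' Mine the top-k discriminative subgraph patterns (gMSV)
#'
#' Depth-first branch-and-bound search over the canonical DFS-code tree of
#' frequent connected subgraphs, keeping the k patterns with the smallest
#' gSide scores. The subtree below a visited pattern is skipped whenever the
#' pattern's gSide lower bound reaches the current worst kept score; the
#' bound's supergraph guarantee makes the pruned search return exactly the
#' same patterns and scores as exhaustive scoring of all frequent patterns.
#'
#' @param dataset a \code{\link{graph_dataset}} with labels in
#'   \code{{-1, +1, NA}}.
#' @param views list of \code{\link{side_view}} objects (may be empty when
#'   labels are present).
#' @param k number of patterns to keep (>= 1).
#' @param min_sup minimum support fraction in \code{(0, 1]}.
#' @param max_edges optional cap on pattern edge count.
#' @param include_singletons score single-vertex patterns (default TRUE).
#' @param min_count absolute support count overriding \code{min_sup}.
#' @param prune use the lower-bound pruning rule (default TRUE); with
#'   \code{FALSE} this is the unpruned reference search.
#' @param lap optionally a precomputed \code{guidance_laplacian}; built from
#'   \code{dataset} and \code{views} when missing.
#' @return object of class \code{mining_result}: \code{patterns} (list of
#'   \code{subgraph_pattern}, ascending gSide score), \code{scores},
#'   \code{bounds}, \code{theta_trace}, \code{stats} (visited /
#'   pruned-by-bound / frequency and canonicality skips), and \code{config}.
#' @export
mine_top_k <- function(dataset, views = list(), k = 10, min_sup = 0.3,
                       max_edges = Inf, include_singletons = TRUE,
                       min_count = NULL, prune = TRUE, lap = NULL) {
  stopifnot(inherits(dataset, "graph_dataset"))
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (is.null(min_count)) {
    if (!is.numeric(min_sup) || min_sup <= 0 || min_sup > 1)
      stop("min_sup must lie in (0, 1]")
    min_count <- as.integer(ceiling(min_sup * dataset$n))
  }
  min_count <- max(1L, as.integer(min_count))
  if (is.null(lap)) lap <- guidance_laplacian(dataset, views)

  topk <- list()          # entries: pattern, q, qhat, code, root_label
  theta <- Inf
  theta_trace <- numeric(0)

  worst_index <- function() {
    qs <- vapply(topk, `[[`, numeric(1), "q")
    cand <- which(qs == max(qs))
    if (length(cand) == 1L) return(cand)
    # among equal worst scores, the lexicographically largest code goes first
    worst <- cand[1L]
    for (i in cand[-1L]) {
      if (cmp_pattern_identity(topk[[i]]$code, topk[[i]]$root_label,
                               topk[[worst]]$code,
                               topk[[worst]]$root_label) > 0L)
        worst <- i
    }
    worst
  }

  visit <- function(pattern, node) {
    q <- gside_score(pattern, lap)
    qhat <- gside_lower_bound(pattern, lap)
    entry <- list(pattern = pattern, q = q, qhat = qhat,
                  code = pattern$code, root_label = node$root_label)
    if (length(topk) < k) {
      topk[[length(topk) + 1L]] <<- entry
      if (length(topk) == k) {
        theta <<- max(vapply(topk, `[[`, numeric(1), "q"))
        theta_trace <<- c(theta_trace, theta)
      }
    } else if (q < theta) {
      topk[[worst_index()]] <<- entry
      theta <<- max(vapply(topk, `[[`, numeric(1), "q"))
      theta_trace <<- c(theta_trace, theta)
    }
    prune && length(topk) == k && qhat >= theta
  }

  stats <- gspan_walk(dataset, min_count, visit, max_edges = max_edges,
                      include_singletons = include_singletons)

  # sort ascending by score, ties by canonical code
  if (length(topk) > 1L) {
    ord <- seq_along(topk)
    for (a in seq_len(length(topk) - 1L)) {
      best <- a
      for (b in (a + 1L):length(topk)) {
        ea <- topk[[ord[best]]]; eb <- topk[[ord[b]]]
        if (eb$q < ea$q ||
            (eb$q == ea$q &&
             cmp_pattern_identity(eb$code, eb$root_label,
                                  ea$code, ea$root_label) < 0L))
          best <- b
      }
      if (best != a) ord[c(a, best)] <- ord[c(best, a)]
    }
    topk <- topk[ord]
  }

  structure(list(
    patterns = lapply(topk, `[[`, "pattern"),
    scores = vapply(topk, `[[`, numeric(1), "q"),
    bounds = vapply(topk, `[[`, numeric(1), "qhat"),
    theta_trace = theta_trace,
    stats = stats,
    config = list(k = k, min_sup = if (exists("min_sup")) min_sup else NA,
                  min_count = min_count, max_edges = max_edges,
                  include_singletons = include_singletons, prune = prune,
                  n = dataset$n,
                  lambda = vapply(views, function(v) v$weight, numeric(1)))),
    class = "mining_result")
}

#' Unpruned reference search
#'
#' Enumerates and scores every frequent pattern, keeping the k best — the
#' reference against which the pruned search is validated, and the baseline
#' for measuring how much work the lower bound saves
#' (\code{stats$visited} counts explored patterns in both modes).
#'
#' @inheritParams mine_top_k
#' @return a \code{mining_result}.
#' @export
mine_top_k_exhaustive <- function(dataset, views = list(), k = 10,
                                  min_sup = 0.3, max_edges = Inf,
                                  include_singletons = TRUE,
                                  min_count = NULL, lap = NULL) {
  mine_top_k(dataset, views, k = k, min_sup = min_sup, max_edges = max_edges,
             include_singletons = include_singletons, min_count = min_count,
             prune = FALSE, lap = lap)
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("<mining_result: %d pattern(s); visited %d, pruned subtrees %d>\n",
              length(x$patterns), x$stats$visited, x$stats$pruned_bound))
  if (length(x$scores) > 0L) {
    for (i in seq_len(min(length(x$scores), 10L))) {
      p <- x$patterns[[i]]
      cat(sprintf("  %2d. q = %+.5f  (%d vertices, %d edges, support %d)\n",
                  i, x$scores[i], n_vertices(p$graph), n_edges(p$graph),
                  length(p$support)))
    }
    if (length(x$scores) > 10L) cat("  ...\n")
  }
  invisible(x)
}
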