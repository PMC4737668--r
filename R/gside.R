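#' gSide score of a subgraph pattern
#'
#' The gSide criterion scores a pattern by the Laplacian quadratic form
#' \code{q(g) = f' L f}, where \code{f} is the pattern's binary occurrence
#' vector over the dataset and \code{L} the guidance Laplacian combining
#' label constraints and side-view similarity structure. Lower is better: a
#' pattern whose support separates dissimilar subjects and groups similar
#' ones gets a negative score. Because \code{f} is binary the quadratic form
#' reduces to the sum of \code{L[p, q]} over pairs of supporting graphs,
#' which is how it is computed (equivalent to the dense product, and cheaper
#' at tens of graphs).
#'
#' @param pattern a \code{subgraph_pattern} (or anything with a
#'   \code{support} field / an integer support vector).
#' @param lap a \code{guidance_laplacian}.
#' @return numeric score.
#' @export
gside_score <- function(pattern, lap) {
  support_quadform(pattern, lap, "L")
}

#' Lower bound of gSide over all supergraphs
#'
#' Computes \code{qhat(g) = f' Lhat f} with \code{Lhat = pmin(0, L)}. For any
#' supergraph \code{g'} of \code{g}, \code{q(g') >= qhat(g)}: a supergraph's
#' support is a subset of \code{g}'s (anti-monotonicity), \code{Lhat <= L}
#' elementwise, and dropping pairs from a sum of non-positive terms can only
#' increase it. The bound licenses pruning the whole enumeration subtree
#' below \code{g} once \code{qhat(g)} cannot beat the current top-k
#' threshold.
#'
#' @inheritParams gside_score
#' @return numeric lower bound, \code{<= gside_score(pattern, lap)}.
#' @export
gside_lower_bound <- function(pattern, lap) {
  support_quadform(pattern, lap, "Lhat")
}

support_quadform <- function(pattern, lap, which) {
  stopifnot(inherits(lap, "guidance_laplacian"))
  support <- if (inherits(pattern, "subgraph_pattern")) pattern$support
             else as.integer(pattern)
  if (inherits(pattern, "subgraph_pattern") &&
      length(pattern$indicator) != lap$n)
    stop("pattern indicator length does not match the Laplacian")
  if (length(support) == 0L) return(0)
  if (any(support < 1L) || any(support > lap$n))
    stop("support indices out of range for the Laplacian")
  sum(lap[[which]][support, support])
}
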