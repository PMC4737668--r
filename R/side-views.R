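#' Construct a side view
#'
#' A side view is a per-subject table of vector-valued measures (clinical,
#' immunologic, serologic, cognitive, ...) auxiliary to the graph
#' representation, with a kernel expressing pairwise subject similarity and a
#' non-negative weight controlling its contribution to the guidance
#' Laplacian.
#'
#' @param features numeric n x d matrix (rows = subjects, in dataset order).
#' @param weight non-negative view weight lambda (default 1).
#' @param kernel_kind kernel identifier; \code{"rbf"} is the default.
#' @param normalize min-max normalize the columns before use (default TRUE,
#'   the standard preprocessing before the RBF kernel).
#' @param name optional view name.
#' @return object of class \code{side_view}.
#' @export
side_view <- function(features, weight = 1, kernel_kind = "rbf",
                      normalize = TRUE, name = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (ncol(features) < 1L) stop("a side view needs at least one feature")
  if (anyNA(features) || any(!is.finite(features)))
    stop("side-view features must be finite and complete")
  if (!is.numeric(weight) || weight < 0) stop("view weight must be >= 0")
  if (normalize) features <- minmax_normalize(features)
  structure(list(features = features, weight = as.numeric(weight),
                 kernel_kind = kernel_kind, name = name),
            class = "side_view")
}

#' @export
print.side_view <- function(x, ...) {
  cat(sprintf("<side_view%s: %d subjects x %d measures, lambda = %g, kernel = %s>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$features), ncol(x$features), x$weight, x$kernel_kind))
  invisible(x)
}

#' Min-max normalization of feature columns
#'
#' Rescales each column to \code{[0, 1]} by \code{(x - min) / (max - min)}.
#' Constant columns map to 0.
#'
#' @param features numeric matrix (or vector, treated as one column).
#' @return matrix of the same shape.
#' @export
minmax_normalize <- function(features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  for (j in seq_len(ncol(features))) {
    lo <- min(features[, j]); hi <- max(features[, j])
    features[, j] <- if (hi > lo) (features[, j] - lo) / (hi - lo) else 0
  }
  features
}

#' RBF kernel matrix of a side view
#'
#' Computes \code{k[i, j] = exp(-||z_i - z_j||^2 / d)} where \code{d} is the
#' dimensionality of the view (the denominator scales the squared distance so
#' the kernel bandwidth tracks the feature count). The mean \code{mu} over
#' all \code{n^2} entries (diagonal included) is stored alongside; it is the
#' similar/dissimilar split point used by \code{\link{theta_matrix}}.
#'
#' @param view a \code{\link{side_view}}, or a numeric matrix of features.
#' @return object of class \code{kernel_matrix} with components \code{k}
#'   (n x n symmetric) and \code{mu}.
#' @export
rbf_kernel <- function(view) {
  z <- if (inherits(view, "side_view")) view$features else as.matrix(view)
  n <- nrow(z); d <- ncol(z)
  sq <- rowSums(z^2)
  dist2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  dist2[dist2 < 0] <- 0  # numerical guard
  k <- exp(-dist2 / d)
  k <- (k + t(k)) / 2
  structure(list(k = k, mu = mean(k)), class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix: %d x %d, mean %.4f>\n",
              nrow(x$k), ncol(x$k), x$mu))
  invisible(x)
}

kernel_of <- function(view) {
  if (inherits(view, "kernel_matrix")) return(view)
  if (!inherits(view, "side_view")) stop("expected a side_view")
  if (!identical(view$kernel_kind, "rbf"))
    stop("unknown kernel kind: ", view$kernel_kind)
  rbf_kernel(view)
}

#' Side-view guidance matrix Theta
#'
#' Splits subject pairs into similar (\code{k[i, j] >= mu}) and dissimilar
#' (\code{k[i, j] < mu}) and assigns \code{+1/|H|} and \code{-1/|L|}
#' respectively, balancing the total mass contributed by the two groups (all
#' entries sum to 0). Ties at the mean count as similar.
#'
#' @param kernel a \code{kernel_matrix} (or \code{side_view}, kernelized
#'   first).
#' @return n x n numeric matrix.
#' @export
theta_matrix <- function(kernel) {
  kernel <- kernel_of(kernel)
  k <- kernel$k
  high <- k >= kernel$mu
  nH <- sum(high); nL <- sum(!high)
  if (nH == 0L || nL == 0L)
    stop("degenerate side view: kernel matrix is constant")
  theta <- matrix(-1 / nL, nrow(k), ncol(k))
  theta[high] <- 1 / nH
  theta
}

#' Supervision matrix Omega from class labels
#'
#' Over ordered subject pairs (diagonal included): same-label pairs get
#' \code{+1/|M|}, different-label pairs \code{-1/|C|}, pairs involving an
#' unlabeled subject 0.
#'
#' @param labels vector in \code{{-1, +1, NA}}.
#' @return n x n numeric matrix.
#' @export
omega_matrix <- function(labels) {
  labels <- as.numeric(labels)
  n <- length(labels)
  yy <- outer(labels, labels)        # NA propagates for unlabeled
  omega <- matrix(0, n, n)
  if (all(is.na(yy))) return(omega)
  m_set <- !is.na(yy) & yy > 0
  c_set <- !is.na(yy) & yy < 0
  if (sum(m_set) == 0L || sum(c_set) == 0L)
    stop("labels present but single-class: need both same- and different-label pairs")
  omega[m_set] <- 1 / sum(m_set)
  omega[c_set] <- -1 / sum(c_set)
  omega
}

#' Combine supervision and side views into the guidance Laplacian
#'
#' Forms \code{Phi = Omega + sum_p lambda_p Theta_p}, the degree matrix
#' \code{D = diag(rowSums(Phi))}, the (signed) Laplacian \code{L = D - Phi}
#' and its elementwise truncation \code{Lhat = pmin(0, L)} used by the score
#' lower bound. Every row of \code{L} sums to zero; \code{Lhat <= L} and
#' \code{Lhat <= 0} elementwise. Because \code{Phi} carries negative entries
#' for dissimilar pairs, \code{L} is a signed Laplacian and need not be
#' positive semi-definite.
#'
#' @param omega n x n supervision matrix (see \code{\link{omega_matrix}}).
#' @param theta_list list of n x n view matrices (see
#'   \code{\link{theta_matrix}}); may be empty.
#' @param weights numeric vector of non-negative view weights aligned with
#'   \code{theta_list}.
#' @return object of class \code{guidance_laplacian} with components
#'   \code{theta_list}, \code{omega}, \code{phi}, \code{degree}, \code{L} and
#'   \code{Lhat}.
#' @export
build_laplacian <- function(omega, theta_list = list(), weights = NULL) {
  omega <- as.matrix(omega)
  n <- nrow(omega)
  if (ncol(omega) != n) stop("omega must be square")
  if (is.null(weights)) weights <- rep(1, length(theta_list))
  if (length(weights) != length(theta_list))
    stop("one weight per theta matrix required")
  if (any(weights < 0)) stop("view weights must be >= 0")
  phi <- omega
  for (p in seq_along(theta_list)) {
    th <- as.matrix(theta_list[[p]])
    if (!all(dim(th) == c(n, n))) stop("theta matrix ", p, " has wrong shape")
    phi <- phi + weights[p] * th
  }
  deg <- rowSums(phi)
  L <- diag(deg, n) - phi
  Lhat <- pmin(L, 0)
  structure(list(theta_list = theta_list, omega = omega, phi = phi,
                 degree = deg, L = L, Lhat = Lhat, n = n),
            class = "guidance_laplacian")
}

#' @export
print.guidance_laplacian <- function(x, ...) {
  cat(sprintf("<guidance_laplacian: n = %d, %d side view(s)>\n",
              x$n, length(x$theta_list)))
  invisible(x)
}

#' Guidance Laplacian from a dataset and its side views
#'
#' Convenience wrapper: kernelizes every view, builds its Theta matrix,
#' builds Omega from the dataset labels (zero matrix when no labels), and
#' combines them with the views' weights.
#'
#' @param dataset a \code{\link{graph_dataset}}.
#' @param views list of \code{\link{side_view}} objects (may be empty).
#' @param use_labels include the supervision term (default TRUE when any
#'   label is present).
#' @return a \code{guidance_laplacian}.
#' @export
guidance_laplacian <- function(dataset, views = list(),
                               use_labels = any(!is.na(dataset$labels))) {
  stopifnot(inherits(dataset, "graph_dataset"))
  if (inherits(views, "side_view")) views <- list(views)
  for (v in views) {
    if (!inherits(v, "side_view")) stop("views must be side_view objects")
    if (nrow(v$features) != dataset$n)
      stop("side view rows must align with the dataset")
  }
  if (length(views) == 0L && !use_labels)
    stop("no guidance available: no side views and no labels")
  omega <- if (use_labels) omega_matrix(dataset$labels)
           else matrix(0, dataset$n, dataset$n)
  theta_list <- lapply(views, function(v) theta_matrix(kernel_of(v)))
  build_laplacian(omega, theta_list, vapply(views, `[[`, numeric(1), "weight"))
}

#' Side-information consistency test
#'
#' Tests whether same-label subject pairs are more similar in a side view
#' than different-label pairs: a two-sample one-tailed t test of H0
#' \code{mu_s - mu_d <= 0} against H1 \code{mu_s - mu_d > 0}, on equally
#' sized samples drawn without replacement from the within-class and
#' between-class kernel similarities. Similarities are taken over unordered
#' pairs \code{i < j} (the diagonal, identically 1 for the RBF kernel, is
#' excluded). Welch's unequal-variance statistic is the default.
#'
#' @param kernel a \code{kernel_matrix} or \code{side_view}.
#' @param labels vector in \code{{-1, +1, NA}}; unlabeled subjects are
#'   dropped.
#' @param sample_size \code{"auto"} (the smaller group size) or an integer.
#' @param seed integer seed for the subsampling; \code{NULL} uses the current
#'   RNG state.
#' @param var_equal use the pooled-variance statistic instead of Welch's.
#' @return list with \code{statistic}, \code{p_value}, \code{df},
#'   \code{n_same}, \code{n_diff}, \code{sample_size}.
#' @export
consistency_test <- function(kernel, labels, sample_size = "auto",
                             seed = NULL, var_equal = FALSE) {
  kernel <- kernel_of(kernel)
  k <- kernel$k
  labels <- as.numeric(labels)
  n <- length(labels)
  if (nrow(k) != n) stop("labels must align with the kernel matrix")
  ut <- upper.tri(k)
  yy <- outer(labels, labels)
  a_s <- k[ut & !is.na(yy) & yy > 0]
  a_d <- k[ut & !is.na(yy) & yy < 0]
  if (length(a_s) == 0L || length(a_d) == 0L)
    stop("need both within-class and between-class pairs")
  size <- if (identical(sample_size, "auto"))
    min(length(a_s), length(a_d)) else as.integer(sample_size)
  if (size < 2L) stop("sample size too small for a t test")
  if (size > min(length(a_s), length(a_d)))
    stop("sample size exceeds the smaller pair group")
  draw <- function(x) {
    if (length(x) == size) x else x[sample.int(length(x), size)]
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  xs <- draw(a_s); xd <- draw(a_d)
  if (stats::var(xs) == 0 && stats::var(xd) == 0) {
    # degenerate: constant samples; identical means give the symmetric null
    stat <- 0
    return(list(statistic = 0, p_value = 0.5, df = NA_real_,
                n_same = length(a_s), n_diff = length(a_d),
                sample_size = size))
  }
  ht <- stats::t.test(xs, xd, alternative = "greater", var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n_same = length(a_s),
       n_diff = length(a_d), sample_size = size)
}
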