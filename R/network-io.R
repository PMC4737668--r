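# Reading weighted connectivity matrices and turning them into binary
# labeled graphs. One matrix file per subject; a manifest CSV
# (subject_id, path, label) binds the dataset and fixes subject order for
# every downstream structure (kernel rows, indicator vectors).

#' Read a square connectivity matrix from CSV/TSV
#'
#' Accepts a plain square numeric block, optionally with a header row and/or
#' a leading column of region names. Asymmetry beyond tolerance is resolved
#' by averaging \code{(w + t(w)) / 2} with a warning. The diagonal carries no
#' information (no self-connections) and is zeroed.
#'
#' @param path file path; comma or tab separated (sniffed from the first
#'   line).
#' @param subject_id optional subject identifier stored on the object.
#' @param tol asymmetry tolerance before the averaging warning fires.
#' @return object of class \code{connectivity_matrix} with \code{weights},
#'   \code{region_names}, \code{subject_id}.
#' @export
read_connectivity_matrix <- function(path, subject_id = NULL, tol = 1e-8) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !grepl("^[-0-9.eE+\t, ]+$", first)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  region_names <- NULL
  if (ncol(df) >= 1L && !is.numeric(df[[1L]])) {
    region_names <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    stop("non-numeric column ", bad, " in ", path)
  }
  w <- as.matrix(df)
  if (nrow(w) != ncol(w))
    stop(sprintf("connectivity matrix in %s is %d x %d, not square",
                 path, nrow(w), ncol(w)))
  if (is.null(region_names)) {
    region_names <- if (has_header) colnames(df) else
      as.character(seq_len(ncol(w)) - 1L)
  }
  if (max(abs(w - t(w))) > tol) {
    warning("asymmetric connectivity matrix in ", path,
            "; symmetrized by averaging")
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(region_names, region_names)
  structure(list(weights = w, region_names = region_names,
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix%s: %d regions>\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              length(x$region_names)))
  invisible(x)
}

#' Min-max normalize link weights
#'
#' Rescales the off-diagonal weights of the whole matrix to \code{[0, 1]}
#' (the DTI convention before thresholding).
#'
#' @param matrix a \code{connectivity_matrix}.
#' @return a \code{connectivity_matrix} with rescaled weights.
#' @export
normalize_link_weights <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  w <- matrix$weights
  off <- w[upper.tri(w) | lower.tri(w)]
  lo <- min(off); hi <- max(off)
  if (hi <= lo) stop("constant off-diagonal weights cannot be normalized")
  w2 <- (w - lo) / (hi - lo)
  diag(w2) <- 0
  matrix$weights <- w2
  matrix
}

#' Threshold a connectivity matrix into a binary labeled graph
#'
#' An undirected edge joins regions \code{u, v} when the link weight exceeds
#' the threshold (strict \code{>} by default; set \code{strict = FALSE} for
#' \code{>=}). Vertex labels are the region indices \code{1..m}, so
#' isomorphic patterns correspond to the same anatomical regions across
#' subjects. Isolated vertices are retained. Negative weights never become
#' edges (positive correlations are the links).
#'
#' @param matrix a \code{connectivity_matrix}.
#' @param threshold link-weight cutoff; 0.9 is the usual fMRI correlation
#'   cutoff, 0.3 the DTI one (after min-max normalization).
#' @param strict use strict inequality (default) rather than \code{>=}.
#' @return a \code{\link{labeled_graph}} with one vertex per region.
#' @export
threshold_to_graph <- function(matrix, threshold = 0.9, strict = TRUE) {
  stopifnot(inherits(matrix, "connectivity_matrix"), is.finite(threshold))
  w <- matrix$weights
  m <- nrow(w)
  keep <- if (strict) w > threshold else w >= threshold
  keep <- keep & w > 0  # positive-weight convention
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  labeled_graph(seq_len(m),
                if (nrow(idx) > 0L) idx else NULL)
}

#' Read a brain-network dataset through a manifest
#'
#' The manifest CSV has columns \code{subject_id}, \code{path} (connectivity
#' matrix file, relative paths resolved against the manifest's directory) and
#' optionally \code{label} in \code{{-1, +1}}. Row order fixes the dataset
#' order everywhere.
#'
#' @param manifest path to the manifest CSV.
#' @param threshold,strict forwarded to \code{\link{threshold_to_graph}}.
#' @param normalize min-max normalize link weights before thresholding.
#' @return a \code{\link{graph_dataset}}.
#' @export
read_brain_dataset <- function(manifest, threshold = 0.9, strict = TRUE,
                               normalize = FALSE) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(df)))
    stop("manifest needs subject_id and path columns")
  base <- dirname(manifest)
  graphs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    cm <- read_connectivity_matrix(p, subject_id = df$subject_id[i])
    if (normalize) cm <- normalize_link_weights(cm)
    graphs[[i]] <- threshold_to_graph(cm, threshold, strict)
  }
  labels <- if ("label" %in% names(df)) as.numeric(df$label) else NULL
  graph_dataset(graphs, labels = labels, ids = df$subject_id)
}

#' Read a side-view CSV aligned to subject IDs
#'
#' First column is the subject ID; remaining numeric columns are the
#' measures. Rows are reordered to match \code{ids}; in strict mode any
#' mismatch between the file's IDs and \code{ids} is an error.
#'
#' @param path CSV path.
#' @param ids character vector of subject IDs in dataset order.
#' @param weight,kernel_kind,normalize forwarded to \code{\link{side_view}}.
#' @param strict error on ID mismatch (default TRUE).
#' @return a \code{\link{side_view}}.
#' @export
read_side_view_csv <- function(path, ids, weight = 1, kernel_kind = "rbf",
                               normalize = TRUE, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  file_ids <- as.character(df[[1L]])
  if (strict && !setequal(file_ids, ids))
    stop("subject IDs in ", path, " do not match the dataset")
  hit <- match(ids, file_ids)
  if (anyNA(hit))
    stop("side view ", path, " is missing subjects: ",
         paste(ids[is.na(hit)], collapse = ", "))
  feats <- as.matrix(df[hit, -1L, drop = FALSE])
  storage.mode(feats) <- "double"
  rownames(feats) <- ids
  side_view(feats, weight = weight, kernel_kind = kernel_kind,
            normalize = normalize,
            name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a label CSV (subject_id, label)
#'
#' @param path two-column CSV with labels in \code{{-1, +1}}.
#' @param ids subject IDs in dataset order.
#' @return numeric label vector aligned with \code{ids}.
#' @export
read_labels_csv <- function(path, ids) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hit <- match(ids, as.character(df[[1L]]))
  if (anyNA(hit))
    stop("labels file is missing subjects: ",
         paste(ids[is.na(hit)], collapse = ", "))
  labels <- as.numeric(df[[2L]][hit])
  if (any(!labels %in% c(-1, 1), na.rm = TRUE))
    stop("labels must be -1 or +1")
  labels
}

pattern_to_edge_list <- function(pattern) {
  g <- pattern$graph
  if (n_edges(g) == 0L) {
    list(vertices = as.list(g$vlabels), edges = list())
  } else {
    list(vertices = as.list(g$vlabels),
         edges = lapply(seq_len(n_edges(g)), function(e)
           list(from = g$vlabels[g$edges[e, 1L]],
                to = g$vlabels[g$edges[e, 2L]],
                edge_label = g$elabels[e])))
  }
}

#' Write a mining result to JSON
#'
#' Emits per-pattern region-label edge lists, gSide score and lower bound,
#' supporting subject IDs, plus the search statistics and configuration.
#'
#' @param result a \code{mining_result}.
#' @param path output file.
#' @param ids optional subject IDs for support reporting.
#' @return \code{path}, invisibly.
#' @export
write_mining_result_json <- function(result, path, ids = NULL) {
  stopifnot(inherits(result, "mining_result"))
  pats <- lapply(seq_along(result$patterns), function(i) {
    p <- result$patterns[[i]]
    c(pattern_to_edge_list(p),
      list(gside = result$scores[i],
           gside_lower_bound = result$bounds[i],
           support = if (is.null(ids)) p$support else ids[p$support]))
  })
  out <- list(patterns = pats, stats = result$stats,
              config = result$config, theta_trace = result$theta_trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a pattern to GraphML
#'
#' Requires the igraph package; vertex labels are stored as the
#' \code{region} attribute.
#'
#' @param pattern a \code{subgraph_pattern} or \code{labeled_graph}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pattern_graphml <- function(pattern, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the igraph package")
  g <- if (inherits(pattern, "subgraph_pattern")) pattern$graph else pattern
  ig <- igraph::make_empty_graph(n = n_vertices(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "region", value = g$vlabels)
  if (n_edges(g) > 0L)
    ig <- igraph::add_edges(ig, t(g$edges))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
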