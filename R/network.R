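#' Build an undirected network from an edge table
#'
#' Networks in fragnet are plain [igraph] graphs: undirected, simple (no
#' self-loops or duplicate edges), with a character `name` attribute on every
#' vertex. Optional per-vertex attributes `class` (a binary flag used only for
#' display, e.g. over-expressed in one of two conditions) and `label` are
#' carried along.
#'
#' @param edges Data frame whose first two columns are vertex ids (character);
#'   extra columns are ignored.
#' @param vertices Optional data frame of vertices; first column vertex id,
#'   optional columns `class` (0/1) and `label`. Vertices mentioned here but
#'   absent from `edges` become isolated vertices.
#' @return An undirected simple `igraph` object.
#' @export
#' @examples
#' net <- network_from_edges(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::vcount(net)
network_from_edges <- function(edges, vertices = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) abort("edge table needs at least two columns")
  el <- cbind(as.character(edges[[1]]), as.character(edges[[2]]))
  ids <- unique(c(el[, 1], el[, 2]))
  vdf <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(vertices)) {
    vertices <- as.data.frame(vertices)
    names(vertices)[1] <- "name"
    vertices$name <- as.character(vertices$name)
    extra <- setdiff(vdf$name, vertices$name)
    if (length(extra)) {
      abort(paste0(
        "edge endpoints missing from vertex table: ",
        paste(head(extra, 5), collapse = ", ")
      ))
    }
    vdf <- vertices
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = vdf
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

vertex_names <- function(network) {
  nm <- igraph::V(network)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(network))) else nm
}

check_network <- function(network) {
  if (!igraph::is_igraph(network)) abort("`network` must be an igraph object")
  if (igraph::vcount(network) == 0) abort("empty graph")
  if (igraph::is_directed(network)) abort("`network` must be undirected")
  if (!igraph::is_simple(network)) {
    abort("`network` must be simple (no self-loops or duplicate edges)")
  }
  invisible(network)
}

#' Connected components of a network
#'
#' Partitions the vertex set into its maximal connected components. Blocks are
#' ordered deterministically by their earliest member in the network's vertex
#' order, so the component indices are stable under re-runs and matrix I/O.
#'
#' @param network An undirected simple igraph object.
#' @return A list of character vectors of vertex ids, one per component, of
#'   class `component_partition`.
#' @export
#' @examples
#' net <- network_from_edges(data.frame(a = c("a", "c"), b = c("b", "d")))
#' find_components(net)
find_components <- function(network) {
  check_network(network)
  comp <- igraph::components(network)
  nm <- vertex_names(network)
  # order blocks by the position of their first member in vertex order
  first_pos <- vapply(
    seq_len(comp$no),
    function(k) min(which(comp$membership == k)),
    1L
  )
  ord <- order(first_pos)
  blocks <- lapply(ord, function(k) nm[comp$membership == k])
  structure(blocks, class = "component_partition")
}

# integer component index per vertex, named, in vertex order
component_index <- function(network, partition = find_components(network)) {
  nm <- vertex_names(network)
  idx <- integer(length(nm))
  names(idx) <- nm
  for (k in seq_along(partition)) idx[partition[[k]]] <- k
  idx
}

#' Construct a network by thresholding a similarity matrix
#'
#' The standard route from scored pairwise relations (co-expression,
#' pathway co-membership, functional similarity scores) to a network: connect
#' two vertices when their similarity score strictly exceeds a user-chosen
#' threshold.
#'
#' @param similarity Labeled square symmetric matrix of similarity scores
#'   (any real range); row and column names are the vertex ids.
#' @param threshold Real; an edge \{i, j\} is created iff
#'   `similarity[i, j] > threshold` and `i != j`.
#' @param keep_isolated If `FALSE` (default) vertices left with no edge are
#'   dropped from the network; if `TRUE` they are kept as isolated vertices.
#' @return An undirected simple igraph object.
#' @export
#' @examples
#' s <- matrix(c(1, .9, .5, .9, 1, .5, .5, .5, 1), 3,
#'   dimnames = list(letters[1:3], letters[1:3])
#' )
#' igraph::vcount(threshold_network(s, 0.7))
threshold_network <- function(similarity, threshold, keep_isolated = FALSE) {
  similarity <- check_square_labeled(similarity, "similarity")
  check_symmetric(similarity, tol = 1e-9, what = "similarity")
  ids <- rownames(similarity)
  adj <- similarity > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  if (!keep_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g
}

#' Local clustering coefficients
#'
#' The local clustering coefficient of a vertex is the fraction of its
#' neighbor pairs that are themselves connected — how close the neighborhood
#' is to a clique. The network-level summary is the mean over vertices of
#' degree at least 2 (the coefficient is undefined below that), the
#' Watts-Strogatz convention under which a complete graph scores exactly 1.
#'
#' @param network An undirected simple igraph object.
#' @return A tibble with columns `vertex`, `degree`, `coefficient`
#'   (`NA` for degree < 2), carrying the network average in attribute
#'   `"average"`; [average_clustering_coefficient()] returns just the average.
#' @export
#' @examples
#' tri <- network_from_edges(data.frame(a = c("a", "b", "c"), b = c("b", "c", "a")))
#' average_clustering_coefficient(tri)
local_clustering_coefficient <- function(network) {
  check_network(network)
  deg <- igraph::degree(network)
  cc <- igraph::transitivity(network, type = "local", isolates = "NaN")
  cc[deg < 2] <- NA_real_
  out <- tibble(
    vertex = vertex_names(network),
    degree = as.integer(unname(deg)),
    coefficient = unname(cc)
  )
  attr(out, "average") <- if (any(deg >= 2)) mean(cc[deg >= 2]) else NA_real_
  out
}

#' @rdname local_clustering_coefficient
#' @export
average_clustering_coefficient <- function(network) {
  attr(local_clustering_coefficient(network), "average")
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' @param similarity Labeled square symmetric matrix.
#' @param mode `"one_minus"`: min-max rescale all entries to \[0, 1\] and take
#'   `1 - s`, forcing a zero diagonal (so maximal similarity becomes distance
#'   0 and minimal similarity distance 1); `"identity"`: the input is already
#'   a dissimilarity matrix and is only validated (symmetric, nonnegative,
#'   zero diagonal) and passed through.
#' @return A dissimilarity matrix with the same dimnames.
#' @export
dissimilarity_from_similarity <- function(similarity,
                                          mode = c("one_minus", "identity")) {
  mode <- match.arg(mode)
  similarity <- check_square_labeled(similarity, "similarity")
  check_symmetric(similarity, tol = 1e-9, what = "similarity")
  if (mode == "identity") {
    check_dissimilarity(similarity)
    return(similarity)
  }
  rng <- range(similarity)
  if (diff(rng) < .Machine$double.eps) abort("degenerate similarity")
  d <- 1 - (similarity - rng[1]) / diff(rng)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# ---- matrix validation helpers ----------------------------------------------

check_square_labeled <- function(m, what = "matrix") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort(paste0(what, " must be square"))
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  } else if (is.null(rownames(m))) {
    rownames(m) <- colnames(m)
  } else if (is.null(colnames(m))) {
    colnames(m) <- rownames(m)
  }
  if (!identical(rownames(m), colnames(m))) {
    abort(paste0(what, " row and column labels disagree"))
  }
  storage.mode(m) <- "double"
  m
}

check_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (!all(is.finite(m))) abort(paste0(what, " has non-finite entries"))
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort(paste0(
      what, " is not symmetric: worst pair (",
      rownames(m)[w[1]], ", ", colnames(m)[w[2]], ") differs by ",
      format(max(asym))
    ))
  }
  invisible(m)
}

check_dissimilarity <- function(D, tol = 1e-12) {
  D <- check_square_labeled(D, "dissimilarity matrix")
  check_symmetric(D, tol = tol, what = "dissimilarity matrix")
  if (any(D < 0)) abort("dissimilarity matrix has negative entries")
  if (any(abs(diag(D)) > tol)) {
    abort("dissimilarity matrix has a nonzero diagonal")
  }
  D
}

# subset + reorder D to the network's vertices, label-checked
align_dissimilarity <- function(D, network) {
  D <- check_dissimilarity(D)
  nm <- vertex_names(network)
  missing <- setdiff(nm, rownames(D))
  if (length(missing)) {
    abort(paste0(
      "dissimilarity matrix is missing vertices: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  D[nm, nm, drop = FALSE]
}
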