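#' Fruchterman-Reingold layout of a connected component
#'
#' Classical force-directed layout in its original 1991 form: attractive
#' forces `d^2/k` along edges, repulsive forces `k^2/d` between all vertex
#' pairs, ideal edge length `k = sqrt(area/n)` on a unit-square frame, and a
#' displacement cap that cools linearly to zero over the iteration budget.
#' The finished layout is translated so its centroid sits at the origin —
#' the centered internal coordinate system that the component-placement stage
#' relies on.
#'
#' @param component A connected undirected simple igraph object.
#' @param iterations Number of cooling iterations (default 500).
#' @param seed Integer seed; the initial positions are drawn uniformly in the
#'   unit square from this seed, so the result is fully reproducible.
#' @return A tibble with columns `vertex`, `x`, `y`, centered at the origin.
#' @export
#' @examples
#' ring <- igraph::make_ring(6)
#' igraph::V(ring)$name <- letters[1:6]
#' fr_layout(ring, iterations = 200, seed = 1)
fr_layout <- function(component, iterations = 500, seed = 1) {
  check_network(component)
  if (iterations < 1) abort("`iterations` must be at least 1")
  if (!igraph::is_connected(component)) abort("component must be connected")
  pos <- fr_layout_matrix(component, iterations, seed)
  tibble(vertex = rownames(pos), x = unname(pos[, 1]), y = unname(pos[, 2]))
}

# matrix core: n x 2 coordinates with vertex-id rownames
fr_layout_matrix <- function(component, iterations, seed) {
  n <- igraph::vcount(component)
  nm <- vertex_names(component)
  if (n == 1) {
    return(matrix(0, 1, 2, dimnames = list(nm, c("x", "y"))))
  }
  pos <- withr::with_seed(seed, matrix(runif(2 * n), n, 2))
  A <- igraph::as_adjacency_matrix(component, sparse = FALSE)
  k <- sqrt(1 / n) # ideal length on a unit-area frame
  # initial displacement cap: 0.3 frame widths; linear cooling. A hotter
  # start than the classical width/10 lets small cycles unfold from crossed
  # random starts instead of freezing into them
  t0 <- 0.3
  eps2 <- 1e-24
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- pmax(dx * dx + dy * dy, eps2)
    d <- sqrt(d2)
    coef <- k^2 / d2 - A * d / k
    diag(coef) <- 0
    disp_x <- rowSums(dx * coef)
    disp_y <- rowSums(dy * coef)
    len <- pmax(sqrt(disp_x^2 + disp_y^2), 1e-12)
    temp <- t0 * (iterations - it + 1) / iterations
    scale <- pmin(1, temp / len)
    pos[, 1] <- pos[, 1] + disp_x * scale
    pos[, 2] <- pos[, 2] + disp_y * scale
  }
  pos <- sweep(pos, 2, colMeans(pos))
  dimnames(pos) <- list(nm, c("x", "y"))
  pos
}

#' Center a layout at the origin
#'
#' Subtracts the centroid, preserving all pairwise distances. Idempotent.
#'
#' @param layout A tibble with columns `vertex`, `x`, `y` (as returned by
#'   [fr_layout()]) or a two-column coordinate matrix.
#' @return The same type of object, with mean coordinate (0, 0).
#' @export
center_layout <- function(layout) {
  if (is.matrix(layout)) {
    return(sweep(layout, 2, colMeans(layout)))
  }
  stopifnot(all(c("x", "y") %in% names(layout)))
  layout$x <- layout$x - mean(layout$x)
  layout$y <- layout$y - mean(layout$y)
  layout
}

# tibble layout -> matrix with rownames
layout_matrix <- function(layout) {
  m <- cbind(x = layout$x, y = layout$y)
  rownames(m) <- layout$vertex
  m
}
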