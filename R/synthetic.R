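#' Planted planar benchmark instance
#'
#' Generates the statistical structure of a fragmented biological similarity
#' network with known ground truth: `n_groups` group centers are drawn
#' uniformly in a square of side `2 * between_spread`, subject to a minimum
#' pairwise separation of `between_spread` (rejection sampling; a regular
#' circle of radius `between_spread` is the fallback), so the between-group
#' distance spectrum is heterogeneous as in real functional-similarity data.
#' Points are scattered around their centers with Gaussian spread
#' `within_spread`, and the dissimilarity
#' matrix is the *exact* pairwise Euclidean distance matrix — so `D` is
#' perfectly realizable in the plane (MDS can reach zero stress) and
#' satisfies the triangle inequality, which makes the instance ideal for
#' recovery tests. The network is built by thresholding the similarity
#' `s = 1 / (1 + d)` (monotone in distance) at a connection radius of
#' three-quarters of the within-group spread: edges form only inside groups,
#' and each group shatters into several small components — the degree of
#' fragmentation typical of thresholded gene-function similarity networks.
#'
#' @param n_points Number of vertices.
#' @param n_groups Number of planted groups.
#' @param within_spread Gaussian spread of points around their group center.
#' @param between_spread Radius of the circle of group centers.
#' @param seed Integer seed.
#' @param threshold Similarity threshold for the network; default
#'   `1 / (1 + 0.75 * within_spread)` (connect points closer than
#'   three-quarters of the within-group spread).
#' @return A list of class `planted_instance`: `network` (igraph, isolated
#'   vertices kept), `D` (Euclidean dissimilarity matrix), `similarity`,
#'   `true_groups` (named integer vector), `points` (the generating
#'   coordinates) and `params`.
#' @export
#' @examples
#' inst <- planar_instance(n_points = 30, n_groups = 3, seed = 1)
#' length(find_components(inst$network))
planar_instance <- function(n_points = 60, n_groups = 4,
                            within_spread = 0.5, between_spread = 4,
                            seed = 1, threshold = NULL) {
  if (n_points < n_groups || n_groups < 1) {
    abort("need n_points >= n_groups >= 1")
  }
  groups <- sort(rep_len(seq_len(n_groups), n_points))
  pts <- withr::with_seed(seed, {
    centers <- NULL
    for (try in seq_len(1000)) {
      cand <- matrix(runif(2 * n_groups, 0, 2 * between_spread), n_groups, 2)
      if (n_groups == 1 || min(dist(cand)) >= between_spread) {
        centers <- cand
        break
      }
    }
    if (is.null(centers)) { # fall back to a regular circle
      ang <- 2 * pi * (seq_len(n_groups) - 1) / n_groups
      centers <- between_spread * cbind(cos(ang), sin(ang))
    }
    centers[groups, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_points, sd = within_spread), n_points, 2)
  })
  ids <- sprintf("v%03d", seq_len(n_points))
  rownames(pts) <- ids
  D <- as.matrix(dist(pts))
  if (max(D) < .Machine$double.eps) abort("degenerate similarity")
  similarity <- 1 / (1 + D)
  diag(similarity) <- 1
  threshold <- threshold %||% (1 / (1 + 0.75 * within_spread))
  network <- threshold_network(similarity, threshold, keep_isolated = TRUE)
  structure(
    list(
      network = network,
      D = D,
      similarity = similarity,
      true_groups = setNames(groups, ids),
      points = pts,
      params = list(
        generator = "planar_instance", n_points = n_points,
        n_groups = n_groups, within_spread = within_spread,
        between_spread = between_spread, threshold = threshold, seed = seed
      )
    ),
    class = "planted_instance"
  )
}

#' Block-structured benchmark instance
#'
#' Generates an (ultrametric-like) block dissimilarity matrix: `d_within`
#' for pairs inside the same block, `d_between` across blocks (a scalar, or
#' a symmetric block-level matrix for unequal block separations), plus
#' optional symmetric uniform jitter. Thresholding midway between the within
#' and between levels turns every block into one clique component, so the
#' component structure equals the planted block structure by construction.
#'
#' @param sizes Integer vector of block sizes.
#' @param d_within Within-block dissimilarity (>= 0).
#' @param d_between Between-block dissimilarity: scalar or p x p symmetric
#'   matrix with all entries > `d_within`.
#' @param jitter Half-width of the uniform noise added to every
#'   off-diagonal entry; must be below `(min(d_between) - d_within) / 2` so
#'   the block structure survives thresholding.
#' @param seed Integer seed (used only when `jitter > 0`).
#' @return A `planted_instance` list (see [planar_instance()]); `points` is
#'   `NULL` since the matrix need not be planar.
#' @export
#' @examples
#' inst <- block_dissimilarity(sizes = c(2, 2), d_within = 1, d_between = 4)
#' component_distances(inst$D, find_components(inst$network))
block_dissimilarity <- function(sizes, d_within = 1, d_between = 4,
                                jitter = 0, seed = 1) {
  p <- length(sizes)
  if (p < 1 || any(sizes < 1)) abort("block sizes must be positive")
  if (d_within < 0) abort("d_within must be nonnegative")
  B <- if (is.matrix(d_between)) {
    check_symmetric(d_between, tol = 1e-12, what = "d_between")
    d_between
  } else {
    matrix(d_between, p, p)
  }
  diag(B) <- d_within
  if (min(B[upper.tri(B)], Inf) <= d_within && p > 1) {
    abort("d_between must exceed d_within")
  }
  gap <- if (p > 1) min(B[upper.tri(B)]) - d_within else Inf
  if (jitter < 0 || jitter >= gap / 2) {
    abort("jitter must be below (d_between - d_within) / 2")
  }
  blocks <- rep(seq_len(p), sizes)
  n <- length(blocks)
  D <- B[blocks, blocks, drop = FALSE]
  if (jitter > 0) {
    J <- withr::with_seed(
      seed, matrix(runif(n * n, -jitter, jitter), n, n)
    )
    D <- D + (J + t(J)) / 2
  }
  diag(D) <- 0
  ids <- sprintf("v%03d", seq_len(n))
  dimnames(D) <- list(ids, ids)
  similarity <- 1 / (1 + D)
  diag(similarity) <- 1
  # threshold midway between the within level and the closest between level
  mid <- d_within + gap / 2
  threshold <- if (is.finite(mid)) 1 / (1 + mid) else 0
  network <- threshold_network(similarity, threshold, keep_isolated = TRUE)
  structure(
    list(
      network = network,
      D = D,
      similarity = similarity,
      true_groups = setNames(blocks, ids),
      points = NULL,
      params = list(
        generator = "block_dissimilarity", sizes = sizes,
        d_within = d_within, d_between = d_between, jitter = jitter,
        threshold = threshold, seed = seed
      )
    ),
    class = "planted_instance"
  )
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf(
    "# planted instance (%s): %d vertices, %d groups, %d components\n",
    x$params$generator, nrow(x$D), length(unique(x$true_groups)),
    length(find_components(x$network))
  ))
  invisible(x)
}
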