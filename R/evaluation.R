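#' Layout-distance correlation
#'
#' The quality metric for a fragmented-network layout: the Pearson
#' correlation between the entries of the vertex dissimilarity matrix and the
#' Euclidean distances between the corresponding vertices in the 2-D layout,
#' over *all* vertex pairs (both within and across components). A layout that
#' is a perfect planar realization of `D` scores 1; an arbitrary layout of
#' unrelated points scores near 0. The correlation is invariant under rigid
#' motions and uniform scaling of the layout.
#'
#' @param layout A layout tibble (columns `vertex`, `x`, `y`) or a coordinate
#'   matrix with vertex-id rownames.
#' @param D Labeled dissimilarity matrix covering all layout vertices.
#' @param method_name Optional method label carried into the report.
#' @param seed Optional seed label carried into the report.
#' @return A one-row tibble (class `evaluation_report`): `method_name`,
#'   `pearson_r` (`NA` with `r_defined = FALSE` when either distance vector
#'   is constant), `stress` (sum of squared residuals over all pairs),
#'   `n_pairs`, `seed`.
#' @export
#' @examples
#' pts <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
#' D <- as.matrix(dist(pts))
#' layout_correlation(pts, D)$pearson_r # 1: exact realization
layout_correlation <- function(layout, D, method_name = NA_character_,
                               seed = NA_integer_) {
  m <- if (is.matrix(layout)) layout else layout_matrix(layout)
  D <- check_dissimilarity(D)
  if (is.null(rownames(m))) {
    if (nrow(m) != nrow(D)) abort("layout and D sizes differ")
    rownames(m) <- rownames(D)
  }
  missing <- setdiff(rownames(D), rownames(m))
  if (length(missing)) {
    abort(paste0(
      "layout is missing vertices: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  m <- m[rownames(D), , drop = FALSE]
  up <- upper.tri(D)
  dvec <- D[up]
  lvec <- as.matrix(dist(m))[up]
  defined <- isTRUE(stats::sd(dvec) > 0) && isTRUE(stats::sd(lvec) > 0)
  tibble(
    method_name = method_name,
    pearson_r = if (defined) cor(dvec, lvec) else NA_real_,
    r_defined = defined,
    stress = sum((dvec - lvec)^2),
    n_pairs = length(dvec),
    seed = seed
  )
}

# ---- layout method registry -------------------------------------------------

# Each method maps (network, D, seed, config) -> layout tibble.
# "fr" is classical whole-graph Fruchterman-Reingold (components placed
# arbitrarily), "mds" is SMACOF on the full vertex-level D, "fragviz" /
# "fragviz_exact" are the two-stage pipelines.
layout_method <- function(name) {
  switch(name,
    fr = function(network, D, seed, config) {
      pos <- fr_layout_matrix(network, config$fr_iterations, seed)
      idx <- component_index(network)
      tibble(
        vertex = rownames(pos), component = unname(idx[rownames(pos)]),
        x = pos[, 1], y = pos[, 2]
      )
    },
    mds = function(network, D, seed, config) {
      D <- align_dissimilarity(D, network)
      fit <- smacof_mds(D,
        seed = seed, max_iter = config$mds_max_iter,
        tol = config$mds_tol, init_method = config$mds_init
      )
      idx <- component_index(network)
      tibble(
        vertex = rownames(D), component = unname(idx[rownames(D)]),
        x = fit$conf[, 1], y = fit$conf[, 2]
      )
    },
    fragviz = function(network, D, seed, config) {
      fragviz_layout(network, D, method = "approx", config = config, seed = seed)
    },
    fragviz_exact = function(network, D, seed, config) {
      fragviz_layout(network, D, method = "exact", config = config, seed = seed)
    },
    abort(paste0("unknown layout method: ", name))
  )
}

#' Run one of the registered layout methods
#'
#' Convenience dispatcher used by [fragmentation_sweep()] and the command
#' line: `"fr"` (whole-graph Fruchterman-Reingold baseline, components placed
#' arbitrarily), `"mds"` (SMACOF on the full vertex dissimilarity matrix),
#' `"fragviz"` (two-stage approximation) or `"fragviz_exact"` (two-stage
#' exact simulation).
#'
#' @param method Method name.
#' @param network An undirected simple igraph object.
#' @param D Labeled dissimilarity matrix.
#' @param seed Integer seed.
#' @param config A [fragviz_config()].
#' @return A layout tibble with columns `vertex`, `component`, `x`, `y`.
#' @export
run_layout_method <- function(method, network, D, seed = 1,
                              config = fragviz_config()) {
  layout_method(method)(network, D, seed, config)
}

#' Threshold sweep over network fragmentation
#'
#' Reproduces the fragmentation experiment design: starting from a similarity
#' matrix, networks are built at a series of edge thresholds (isolated
#' vertices kept, so the vertex set is constant), each layout method is run
#' `reps` times with shared derived seeds, and the mean layout-distance
#' correlation is reported per threshold together with the component count
#' and average local clustering coefficient of the thresholded network.
#' Raising the threshold strips edges, so the component count is
#' non-decreasing along the sweep.
#'
#' @param similarity Labeled symmetric similarity matrix.
#' @param thresholds Ascending numeric vector of edge thresholds.
#' @param methods Character vector of method names (see
#'   [run_layout_method()]).
#' @param reps Repetitions per threshold/method (seeds are shared across
#'   methods, so methods are compared on identical starts).
#' @param seed Integer master seed.
#' @param config A [fragviz_config()].
#' @param D Optional vertex dissimilarity matrix; by default derived from
#'   `similarity` via [dissimilarity_from_similarity()].
#' @return A tibble with one row per threshold x method: `threshold`,
#'   `method`, `mean_r`, `n_components`, `clustering_coeff`, `reps`. The
#'   per-repetition correlations are attached as attribute `"runs"`.
#' @export
fragmentation_sweep <- function(similarity, thresholds,
                                methods = c("fr", "fragviz", "mds"),
                                reps = 10, seed = 1,
                                config = fragviz_config(),
                                D = NULL) {
  if (is.unsorted(thresholds)) abort("`thresholds` must be ascending")
  if (reps < 1) abort("`reps` must be at least 1")
  similarity <- check_square_labeled(similarity, "similarity")
  check_symmetric(similarity, tol = 1e-9, what = "similarity")
  D <- D %||% dissimilarity_from_similarity(similarity, mode = "one_minus")
  runs <- purrr::map_dfr(seq_along(thresholds), function(ti) {
    th <- thresholds[ti]
    net <- threshold_network(similarity, th, keep_isolated = TRUE)
    Dn <- align_dissimilarity(D, net)
    n_comp <- length(find_components(net))
    cc <- average_clustering_coefficient(net)
    purrr::map_dfr(seq_len(reps), function(r) {
      rep_seed <- derive_seed(seed, (ti - 1) * reps + r)
      purrr::map_dfr(methods, function(mth) {
        lay <- quiet_scale_warning(
          run_layout_method(mth, net, Dn, seed = rep_seed, config = config)
        )
        rpt <- layout_correlation(lay, Dn, method_name = mth, seed = rep_seed)
        tibble(
          threshold = th, method = mth, rep = r,
          pearson_r = rpt$pearson_r,
          n_components = n_comp, clustering_coeff = cc
        )
      })
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(runs, .data$threshold, .data$method),
    mean_r = mean(.data$pearson_r),
    n_components = .data$n_components[1],
    clustering_coeff = .data$clustering_coeff[1],
    reps = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "runs") <- runs
  out
}

# all-singleton / single-component K defaults are expected mid-sweep
quiet_scale_warning <- function(expr) {
  withCallingHandlers(
    expr,
    fragnet_scale_default = function(w) invokeRestart("muffleWarning")
  )
}

#' Most similar components for overlay rendering
#'
#' For each component, finds its `k_links` nearest components under the
#' average-linkage component distance matrix; duplicate undirected links are
#' merged. The similarity weight used for line widths is
#' `(max(delta) - delta) / max(delta)`, so the closest pair gets the widest
#' line. Ties are broken toward the lower component index.
#'
#' @param delta Component distance matrix ([component_distances()]).
#' @param k_links Number of nearest partners per component (capped at p - 1).
#' @return A tibble: `comp_a`, `comp_b` (`comp_a < comp_b`), `delta`,
#'   `weight`, sorted by component indices.
#' @export
nearest_component_links <- function(delta, k_links = 2) {
  delta <- as.matrix(delta)
  p <- nrow(delta)
  if (p < 2) abort("at least two components required")
  k_links <- min(k_links, p - 1)
  pairs <- purrr::map_dfr(seq_len(p), function(k) {
    others <- setdiff(seq_len(p), k)
    nearest <- others[order(delta[k, others])][seq_len(k_links)]
    tibble(
      comp_a = pmin(k, nearest), comp_b = pmax(k, nearest),
      delta = delta[cbind(k, nearest)]
    )
  })
  pairs <- dplyr::distinct(pairs, .data$comp_a, .data$comp_b, .keep_all = TRUE)
  dmax <- max(delta)
  pairs$weight <- if (dmax > 0) (dmax - pairs$delta) / dmax else 1
  dplyr::arrange(pairs, .data$comp_a, .data$comp_b)
}
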