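#' Two-stage layout of a fragmented network
#'
#' The main entry point. Stage one lays out every connected component
#' internally with the Fruchterman-Reingold algorithm ([fr_layout()]). Stage
#' two places the components as rigid bodies so that their mutual proximity
#' reflects the vertex dissimilarity matrix `D`, using either:
#'
#' * `method = "approx"` (default): component-level average-linkage distances
#'   ([component_distances()]) embedded by SMACOF MDS ([smacof_mds()]), a
#'   size-aware scaling factor ([scaling_factor()]), and an annealed
#'   rotation-only refinement ([optimize_rotations()]); or
#' * `method = "exact"`: the full semi-physical spring simulation
#'   ([simulate_exact()]) that translates and rotates the components until
#'   the net forces vanish.
#'
#' A network with a single component has no placement problem; the result
#' then equals the plain Fruchterman-Reingold layout of the whole graph with
#' the same seed. When every component is a singleton there is no internal
#' layout to preserve and the approximate method reduces to pure MDS of `D`.
#'
#' @param network An undirected simple igraph object.
#' @param D Labeled dissimilarity matrix covering all network vertices
#'   (symmetric, nonnegative, zero diagonal).
#' @param method `"approx"` or `"exact"`.
#' @param config A [fragviz_config()].
#' @param seed Integer seed; the whole pipeline is deterministic given the
#'   seed and inputs.
#' @return A tibble of class `fragviz_layout` with columns `vertex`,
#'   `component`, `x`, `y` (network vertex order). Attributes carry the
#'   [component_placement()], the network, and a `diagnostics` list (final
#'   inter-component stress, layout-distance Pearson correlation, overlap
#'   count of component bounding circles, per-stage timings, engine traces).
#'   Use [glance()] for a one-row summary and [autoplot()] to plot.
#' @export
#' @examples
#' inst <- block_dissimilarity(sizes = c(3, 3), d_within = 1, d_between = 4)
#' lay <- fragviz_layout(inst$network, inst$D, seed = 1)
#' glance(lay)
fragviz_layout <- function(network, D, method = c("approx", "exact"),
                           config = fragviz_config(), seed = 1) {
  method <- match.arg(method)
  check_network(network)
  D <- align_dissimilarity(D, network)
  stamp <- function() proc.time()[["elapsed"]]
  timings <- list()

  t0 <- stamp()
  partition <- find_components(network)
  p <- length(partition)
  timings$components <- stamp() - t0

  t0 <- stamp()
  layouts <- component_layouts(network, partition, config$fr_iterations, seed)
  timings$fr <- stamp() - t0

  trace <- NULL
  if (p == 1) {
    placement <- component_placement(matrix(0, 1, 2), 0, K = 1)
  } else if (method == "approx") {
    t0 <- stamp()
    delta <- component_distances(D, partition)
    mds <- smacof_mds(delta,
      seed = seed, max_iter = config$mds_max_iter,
      tol = config$mds_tol, init_method = config$mds_init
    )
    timings$mds <- stamp() - t0
    t0 <- stamp()
    sizes <- vapply(layouts, nrow, 1L)
    K <- if (all(sizes < 2)) 1 else scaling_factor(layouts, mds$conf)
    rot <- optimize_rotations(
      layouts, mds$conf, K, D,
      partition = partition,
      schedule = anneal_schedule(
        t0 = config$anneal_t0, decay = config$anneal_decay,
        sweeps = config$anneal_sweeps, seed = derive_seed(seed, p + 1)
      ),
      config = config
    )
    timings$rotation <- stamp() - t0
    placement <- component_placement(mds$conf, rot$angles, K = K)
    trace <- rot$trace
  } else {
    t0 <- stamp()
    sim <- simulate_exact(layouts, D, config, seed = seed)
    timings$simulation <- stamp() - t0
    placement <- sim$placement
    trace <- sim$trace
  }

  st <- stack_global(layouts, placement)
  ord <- match(vertex_names(network), rownames(st$G))
  out <- tibble(
    vertex = rownames(st$G)[ord],
    component = st$comp[ord],
    x = unname(st$G[ord, 1]),
    y = unname(st$G[ord, 2])
  )
  report <- layout_correlation(out, D,
    method_name = paste0("fragviz_", method), seed = seed
  )
  diagnostics <- list(
    stress = total_stress(layouts, placement, D),
    pearson_r = report$pearson_r,
    n_components = p,
    K = placement$K,
    overlap_pairs = count_overlaps(layouts, placement),
    timings = tibble(
      stage = names(timings),
      seconds = unlist(timings, use.names = FALSE)
    ),
    trace = trace
  )
  structure(
    out,
    class = c("fragviz_layout", class(out)),
    placement = placement,
    network = network,
    method = method,
    seed = seed,
    diagnostics = diagnostics
  )
}

# pairs of components whose bounding circles intersect (overlap diagnostic)
count_overlaps <- function(layouts, placement) {
  p <- length(layouts)
  if (p < 2) {
    return(0L)
  }
  radii <- vapply(layouts, function(V) {
    if (nrow(V) < 2) 0 else max(sqrt(rowSums(V^2)))
  }, 1)
  centers <- placement$K * placement$centers
  d <- as.matrix(dist(centers))
  sum(d[upper.tri(d)] < outer(radii, radii, "+")[upper.tri(d)])
}

#' @export
print.fragviz_layout <- function(x, ...) {
  diag <- attr(x, "diagnostics")
  cat(sprintf(
    "# fragviz layout (%s): %d vertices in %d component(s)\n",
    attr(x, "method"), nrow(x), diag$n_components
  ))
  cat(sprintf(
    "# stress = %.4g, pearson r = %.3f, K = %.3g\n",
    diag$stress, diag$pearson_r, diag$K
  ))
  NextMethod()
}

#' Tidy a fragviz layout
#'
#' @param x A `fragviz_layout`.
#' @param ... Unused.
#' @return A plain tibble with columns `vertex`, `component`, `x`, `y`.
#' @method tidy fragviz_layout
#' @export
tidy.fragviz_layout <- function(x, ...) {
  as_tibble(unclass(x)[c("vertex", "component", "x", "y")])
}

#' One-row summary of a fragviz layout
#'
#' @param x A `fragviz_layout`.
#' @param ... Unused.
#' @return A one-row tibble: method, vertex/edge/component counts, scaling
#'   factor `K`, inter-component stress, layout-distance Pearson correlation,
#'   bounding-circle overlap count, seed.
#' @method glance fragviz_layout
#' @export
glance.fragviz_layout <- function(x, ...) {
  diag <- attr(x, "diagnostics")
  net <- attr(x, "network")
  tibble(
    method = attr(x, "method"),
    n_vertices = nrow(x),
    n_edges = igraph::ecount(net),
    n_components = diag$n_components,
    K = diag$K,
    stress = diag$stress,
    pearson_r = diag$pearson_r,
    overlap_pairs = diag$overlap_pairs,
    seed = attr(x, "seed")
  )
}

#' Plot a fragviz layout
#'
#' Renders the layout in the usual gene-network idiom: intra-component edges as
#' segments, vertices as solid circles (`class == 1`) or hollow circles
#' (otherwise), optional background lines connecting each component to its
#' most similar components, and component index labels at the centroids.
#'
#' @param object A `fragviz_layout`.
#' @param links Optional tibble from [nearest_component_links()]; drawn as
#'   background lines whose width scales with similarity.
#' @param label_components Draw component indices at component centroids.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fragviz_layout
#' @export
autoplot.fragviz_layout <- function(object, links = NULL,
                                    label_components = FALSE, ...) {
  net <- attr(object, "network")
  coords <- tidy(object)
  el <- igraph::as_edgelist(net)
  pos <- match(el, coords$vertex)
  edges <- tibble(
    x = coords$x[pos[seq_len(nrow(el))]],
    y = coords$y[pos[seq_len(nrow(el))]],
    xend = coords$x[pos[nrow(el) + seq_len(nrow(el))]],
    yend = coords$y[pos[nrow(el) + seq_len(nrow(el))]]
  )
  cls <- igraph::vertex_attr(net, "class")
  coords$class <- if (is.null(cls)) 0 else cls[match(coords$vertex, vertex_names(net))]
  cents <- dplyr::summarise(
    dplyr::group_by(coords, .data$component),
    x = mean(.data$x), y = mean(.data$y), .groups = "drop"
  )
  gg <- ggplot2::ggplot()
  if (!is.null(links) && nrow(links)) {
    seg <- tibble(
      x = cents$x[match(links$comp_a, cents$component)],
      y = cents$y[match(links$comp_a, cents$component)],
      xend = cents$x[match(links$comp_b, cents$component)],
      yend = cents$y[match(links$comp_b, cents$component)],
      weight = links$weight
    )
    gg <- gg + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(.data$x, .data$y,
        xend = .data$xend, yend = .data$yend,
        linewidth = .data$weight
      ),
      color = "steelblue", alpha = 0.5
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none")
  }
  if (nrow(edges)) {
    gg <- gg + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey40"
    )
  }
  gg <- gg + ggplot2::geom_point(
    data = coords,
    ggplot2::aes(.data$x, .data$y, shape = factor(.data$class)),
    size = 2
  ) +
    ggplot2::scale_shape_manual(
      values = c("0" = 1, "1" = 16),
      guide = "none"
    )
  if (label_components) {
    gg <- gg + ggplot2::geom_text(
      data = cents,
      ggplot2::aes(.data$x, .data$y, label = .data$component),
      vjust = -1, color = "grey30", size = 3
    )
  }
  gg + ggplot2::coord_equal() + ggplot2::theme_void()
}
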