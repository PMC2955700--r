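#' Average-linkage distances between components
#'
#' Collapses the vertex-level dissimilarity matrix to the component level:
#' the distance between two components is the mean of all cross-component
#' vertex dissimilarities — exactly the average-linkage inter-cluster
#' distance of hierarchical clustering.
#'
#' @param D Dissimilarity matrix covering all partition vertices (labeled).
#' @param partition A [find_components()] partition (list of vertex-id
#'   vectors).
#' @return A p x p symmetric matrix with zero diagonal; dimnames are the
#'   component indices.
#' @export
component_distances <- function(D, partition) {
  ids <- unlist(partition)
  missing <- setdiff(ids, rownames(D))
  if (length(missing)) {
    abort(paste0(
      "dissimilarity matrix is missing vertices: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  Dm <- D[ids, ids, drop = FALSE]
  grp <- rep(seq_along(partition), lengths(partition))
  sums <- rowsum(t(rowsum(Dm, grp)), grp) # p x p block sums
  sizes <- lengths(partition)
  delta <- sums / outer(sizes, sizes)
  diag(delta) <- 0
  delta <- (delta + t(delta)) / 2
  dimnames(delta) <- list(seq_along(partition), seq_along(partition))
  delta
}

#' SMACOF multidimensional scaling
#'
#' Embeds a symmetric distance matrix in the plane by minimizing the raw
#' stress `sum_{k<l} (delta_kl - ||c_k - c_l||)^2` with the Guttman-transform
#' majorization iteration (unit weights). Majorization guarantees the stress
#' never increases between iterations; the loop stops when the relative
#' stress decrease falls below `tol` or after `max_iter` iterations.
#'
#' @param delta Symmetric nonnegative matrix with zero diagonal.
#' @param init Optional p x 2 starting configuration; otherwise seeded random
#'   points in the unit disk (`init_method = "random"`) or a classical-scaling
#'   (Torgerson) start (`init_method = "torgerson"`).
#' @param seed Integer seed for the random start.
#' @param max_iter,tol Iteration cap and relative stress-change tolerance.
#' @param init_method `"random"` or `"torgerson"`.
#' @return A list of class `smacof_fit`: `conf` (p x 2 configuration),
#'   `stress` (final raw stress), `trace` (stress per iteration, starting
#'   with the initial configuration), `iterations`, `converged`.
#' @export
#' @examples
#' delta <- matrix(c(0, 4, 4, 0), 2)
#' fit <- smacof_mds(delta, seed = 1)
#' dist(fit$conf) # 4
smacof_mds <- function(delta, init = NULL, seed = 1, max_iter = 300,
                       tol = 1e-8, init_method = c("random", "torgerson")) {
  init_method <- match.arg(init_method)
  delta <- as.matrix(delta)
  p <- nrow(delta)
  if (p == 1) {
    return(structure(
      list(
        conf = matrix(0, 1, 2), stress = 0, trace = 0,
        iterations = 0L, converged = TRUE
      ),
      class = "smacof_fit"
    ))
  }
  X <- if (!is.null(init)) {
    matrix(as.numeric(init), ncol = 2)
  } else if (init_method == "torgerson") {
    cs <- cmdscale(delta, k = min(2, p - 1))
    cbind(cs, matrix(0, p, 2 - ncol(cs)))
  } else {
    withr::with_seed(seed, {
      th <- runif(p, 0, 2 * pi)
      r <- sqrt(runif(p))
      cbind(r * cos(th), r * sin(th))
    })
  }
  up <- upper.tri(delta)
  raw_stress <- function(X) {
    d <- as.matrix(dist(X))
    sum((delta[up] - d[up])^2)
  }
  trace <- numeric(max_iter + 1)
  trace[1] <- raw_stress(X)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(X))
    B <- -ifelse(d > 1e-12, delta / d, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / p # Guttman transform (unit weights)
    trace[it + 1] <- raw_stress(X)
    prev <- trace[it]
    if (prev - trace[it + 1] < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      conf = unname(X), stress = trace[it + 1],
      trace = trace[seq_len(it + 1)], iterations = it, converged = converged
    ),
    class = "smacof_fit"
  )
}

#' Global-to-local scaling factor
#'
#' MDS places component centers while ignoring component sizes, so the
#' centers must be spread relative to the fixed internal layouts before the
#' two coordinate systems are combined (`g = R(phi) v + K c`). The rule of
#' thumb is the ratio `K = v_bar / g_bar` of the average component size
#' (mean intra-component pairwise vertex distance, averaged over components
#' with at least two vertices) to the average pairwise center distance.
#'
#' @param layouts List of centered local layouts.
#' @param centers p x 2 matrix of component centers (e.g. [smacof_mds()]
#'   configuration).
#' @return Positive scalar `K`. With a single component, or when every
#'   component is a singleton, component size is undefined and `K = 1` is
#'   returned with a warning (the layout degenerates to pure MDS).
#' @export
scaling_factor <- function(layouts, centers) {
  p <- length(layouts)
  if (p == 1) {
    warn("single component: scaling factor defaults to 1",
      class = "fragnet_scale_default"
    )
    return(1)
  }
  sizes <- vapply(layouts, nrow, 1L)
  if (all(sizes < 2)) {
    warn("all components are singletons: scaling factor defaults to 1",
      class = "fragnet_scale_default"
    )
    return(1)
  }
  v_bar <- mean(vapply(
    layouts[sizes >= 2],
    function(V) mean(dist(V)), 1
  ))
  g_bar <- mean(dist(centers))
  if (g_bar < 1e-12) abort("degenerate MDS solution")
  v_bar / g_bar
}

#' Annealing schedule for the rotation phase
#'
#' @param t0 Initial temperature (`0` disables annealing: greedy descent).
#' @param decay Multiplicative temperature decay per sweep, in (0, 1).
#' @param sweeps Number of sweeps over all components.
#' @param seed Integer seed for the reversal draws.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 1, decay = 0.9, sweeps = 50, seed = 1) {
  stopifnot(t0 >= 0, decay > 0, decay < 1, sweeps >= 1)
  structure(
    list(t0 = t0, decay = decay, sweeps = as.integer(sweeps), seed = seed),
    class = "anneal_schedule"
  )
}

#' Optimize component rotations by simulated annealing
#'
#' With the component centers fixed (from MDS plus scaling), only the
#' orientations remain free. Each sweep visits the components in ascending
#' index order and applies the torque-derived rotation step of the exact
#' simulation, computed from the spring forces in the scaled global system.
#' To escape local minima, the step is applied in the *opposite* ("wrong")
#' direction with probability `exp(-1 / T_t)`, where the temperature decays
#' geometrically per sweep — such reversed moves are accepted even when they
#' raise the stress, while regular moves are reverted if they do. Singleton
#' components experience no torque and keep orientation 0.
#'
#' @param layouts List of centered local layouts.
#' @param centers p x 2 matrix of component centers.
#' @param K Scaling factor from [scaling_factor()].
#' @param D Dissimilarity matrix covering all vertices.
#' @param partition Optional partition (unused beyond validation; the layouts
#'   carry the vertex ids).
#' @param schedule An [anneal_schedule()].
#' @param config A [fragviz_config()] (supplies `step_phi`).
#' @return A list: `angles` (radians, one per component), `trace` (tibble of
#'   stress after each sweep, sweep 0 = initial), `accepted` (move count).
#' @export
optimize_rotations <- function(layouts, centers, K, D, partition = NULL,
                               schedule = anneal_schedule(),
                               config = fragviz_config()) {
  p <- length(layouts)
  placement <- component_placement(centers, rep(0, p), K = K)
  sizes <- vapply(layouts, nrow, 1L)
  n_total <- sum(sizes)
  rotatable <- which(sizes >= 2)
  stress <- total_stress(layouts, placement, D)
  trace <- numeric(schedule$sweeps + 1)
  trace[1] <- stress
  accepted <- 0L
  if (length(rotatable) && p > 1) {
    withr::with_seed(schedule$seed, {
      for (s in seq_len(schedule$sweeps)) {
        temp <- schedule$t0 * schedule$decay^(s - 1)
        p_rev <- if (temp > 0) exp(-1 / temp) else 0
        for (k in rotatable) {
          F <- net_forces(layouts, placement, D)
          upd <- component_update(k, F, layouts, placement, config)
          # same per-spring step normalization as the exact simulation
          n_other <- max(1L, n_total - sizes[k])
          if (abs(upd$dphi) < .Machine$double.eps) next
          reversed <- p_rev > 0 && runif(1) < p_rev
          dphi <- (if (reversed) -upd$dphi else upd$dphi) / n_other
          placement$angles[k] <- placement$angles[k] + dphi
          new_stress <- total_stress(layouts, placement, D)
          if (reversed || new_stress <= stress) {
            stress <- new_stress
            accepted <- accepted + 1L
          } else {
            placement$angles[k] <- placement$angles[k] - dphi
          }
        }
        trace[s + 1] <- stress
      }
    })
  } else {
    trace[] <- stress
  }
  list(
    angles = placement$angles,
    trace = tibble(sweep = 0:schedule$sweeps, stress = trace),
    accepted = accepted
  )
}
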