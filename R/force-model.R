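#' Internal layouts for every component of a network
#'
#' Runs [fr_layout()] on each connected component with a per-component seed
#' derived deterministically from `seed` (the first component receives `seed`
#' itself), returning the centered local coordinate systems that both
#' placement engines consume.
#'
#' @param network An undirected simple igraph object.
#' @param partition Optional [find_components()] result (recomputed if `NULL`).
#' @param iterations Fruchterman-Reingold iterations per component.
#' @param seed Integer seed.
#' @return A list of n_k x 2 coordinate matrices (rownames = vertex ids), one
#'   per component, each centered at the origin.
#' @export
component_layouts <- function(network, partition = NULL,
                              iterations = 500, seed = 1) {
  partition <- partition %||% find_components(network)
  lapply(seq_along(partition), function(k) {
    sub <- igraph::induced_subgraph(
      network, match(partition[[k]], vertex_names(network))
    )
    fr_layout_matrix(sub, iterations, derive_seed(seed, k))
  })
}

#' Rigid-body placement of components
#'
#' @param centers p x 2 matrix of component centers `c_k` (global units).
#' @param angles Numeric vector of rotations `phi_k` in radians.
#' @param K Positive global scaling factor applied to the centers; 1 in the
#'   exact simulation.
#' @return A list of class `component_placement`.
#' @export
component_placement <- function(centers, angles = rep(0, nrow(centers)), K = 1) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (length(angles) != nrow(centers)) {
    abort("one angle per component required")
  }
  if (!is.finite(K) || K <= 0) abort("`K` must be positive and finite")
  if (!all(is.finite(centers)) || !all(is.finite(angles))) {
    abort("placement must be finite")
  }
  structure(
    list(centers = centers, angles = as.numeric(angles), K = K),
    class = "component_placement"
  )
}

#' Map a local vertex position to the global coordinate system
#'
#' `g = R(phi) v + K c`: the local coordinate is rotated by the component's
#' orientation and offset by its (scaled) center. With `phi = 0`, `K = 1`
#' this is plain translation.
#'
#' @param v Length-2 local coordinate.
#' @param phi Rotation in radians (counter-clockwise).
#' @param c Length-2 component center.
#' @param K Scaling factor applied to the center.
#' @return Length-2 global coordinate.
#' @export
#' @examples
#' global_position(c(1, 0), pi / 2, c(0, 0), 1)
global_position <- function(v, phi, c, K = 1) {
  c(
    cos(phi) * v[1] - sin(phi) * v[2] + K * c[1],
    sin(phi) * v[1] + cos(phi) * v[2] + K * c[2]
  )
}

# rotate an n x 2 matrix by phi (CCW)
rotate_coords <- function(m, phi) {
  cs <- cos(phi)
  sn <- sin(phi)
  cbind(cs * m[, 1] - sn * m[, 2], sn * m[, 1] + cs * m[, 2])
}

# stack local layouts: global positions, local (rotated) coords, component ids
stack_global <- function(layouts, placement) {
  ks <- rep(seq_along(layouts), vapply(layouts, nrow, 1L))
  rot <- lapply(seq_along(layouts), function(k) {
    rotate_coords(layouts[[k]], placement$angles[k])
  })
  V <- do.call(rbind, rot)
  G <- V + placement$K * placement$centers[ks, , drop = FALSE]
  rownames(G) <- rownames(V) <- unlist(lapply(layouts, rownames))
  list(G = G, V = V, comp = ks)
}

# deterministic pseudo-random angle for a coincident vertex pair
coincident_angle <- function(i, j) {
  h <- sin(i * 12.9898 + j * 78.233) * 43758.5453
  2 * pi * (h - floor(h))
}

#' Hooke spring force between two globally placed vertices
#'
#' `F_ij = (d_ij - ||g_i - g_j||) (g_i - g_j) / ||g_i - g_j||`: attractive
#' (pulls i toward j) when the current separation exceeds the rest length
#' `d_ij`, repulsive when shorter, zero at rest length. When the two points
#' (numerically) coincide the direction is undefined; a deterministic
#' pseudo-random unit direction with magnitude `d_ij` is substituted and a
#' warning is raised.
#'
#' @param g_i,g_j Length-2 global positions.
#' @param d_ij Nonnegative rest length (the dissimilarity).
#' @param pair Optional integer pair used to seed the coincident-direction
#'   hash (defaults to `c(1, 2)`).
#' @return Length-2 force vector acting on vertex i.
#' @export
#' @examples
#' spring_force(c(0, 0), c(3, 0), 1) # pulls i toward j by 2
spring_force <- function(g_i, g_j, d_ij, pair = c(1L, 2L)) {
  delta <- g_i - g_j
  r <- sqrt(sum(delta^2))
  if (r < 1e-9) {
    warn("coincident vertex positions; substituting a pseudo-random direction",
      class = "fragnet_coincident"
    )
    a <- coincident_angle(min(pair), max(pair))
    dir <- c(cos(a), sin(a))
    if (pair[1] > pair[2]) dir <- -dir
    return(d_ij * dir)
  }
  (d_ij - r) * delta / r
}

#' Net spring forces on every vertex
#'
#' Sums the Hooke forces of all springs attached to each vertex. Springs
#' connect vertices of *different* components only; because a rigid
#' component's internal springs obey Newton's third law, including
#' intra-component pairs would change neither the net force nor the net
#' torque on any component (the `intra` flag exists to verify exactly that).
#'
#' @param layouts List of centered local layouts ([component_layouts()]).
#' @param placement A [component_placement()].
#' @param D Dissimilarity matrix covering all vertices (labeled).
#' @param intra If `TRUE`, intra-component pairs are included in the sum.
#' @return An n x 2 matrix of forces, rownames = vertex ids (component order).
#' @export
net_forces <- function(layouts, placement, D, intra = FALSE) {
  st <- stack_global(layouts, placement)
  G <- st$G
  n <- nrow(G)
  Dm <- D[rownames(G), rownames(G), drop = FALSE]
  dx <- outer(G[, 1], G[, 1], "-")
  dy <- outer(G[, 2], G[, 2], "-")
  r <- sqrt(dx * dx + dy * dy)
  mask <- if (intra) 1 - diag(n) else outer(st$comp, st$comp, "!=") * 1
  coincident <- mask > 0 & r < 1e-9
  rr <- pmax(r, 1e-9)
  C <- (Dm - r) / rr * mask
  C[coincident] <- 0
  F <- cbind(rowSums(C * dx), rowSums(C * dy))
  if (any(coincident)) {
    warn("coincident vertex positions; substituting pseudo-random directions",
      class = "fragnet_coincident"
    )
    idx <- which(coincident & upper.tri(coincident), arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]
      j <- idx[q, 2]
      a <- coincident_angle(i, j)
      f <- Dm[i, j] * c(cos(a), sin(a))
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  rownames(F) <- rownames(G)
  F
}

# one shared distance computation for the simulation loop: inter-component
# forces and the stress in the same pass
forces_and_stress <- function(layouts, placement, D) {
  st <- stack_global(layouts, placement)
  G <- st$G
  n <- nrow(G)
  Dm <- D[rownames(G), rownames(G), drop = FALSE]
  dx <- outer(G[, 1], G[, 1], "-")
  dy <- outer(G[, 2], G[, 2], "-")
  r <- sqrt(dx * dx + dy * dy)
  mask <- outer(st$comp, st$comp, "!=") * 1
  coincident <- mask > 0 & r < 1e-9
  rr <- pmax(r, 1e-9)
  C <- (Dm - r) / rr * mask
  C[coincident] <- 0
  F <- cbind(rowSums(C * dx), rowSums(C * dy))
  if (any(coincident)) {
    warn("coincident vertex positions; substituting pseudo-random directions",
      class = "fragnet_coincident"
    )
    idx <- which(coincident & upper.tri(coincident), arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]
      j <- idx[q, 2]
      a <- coincident_angle(i, j)
      f <- Dm[i, j] * c(cos(a), sin(a))
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  rownames(F) <- rownames(G)
  sel <- mask > 0 & upper.tri(r)
  list(forces = F, stress = sum((Dm[sel] - r[sel])^2))
}

#' Translation and rotation step for one component
#'
#' Converts the net forces on a component's vertices into a rigid-body move:
#' the translation step is proportional to the mean force (uniform vertex
#' mass cancels), the rotation step to the net torque divided by the moment
#' of inertia `sum ||v_i||^2`. Torques are taken about the component center
#' using the *current rotated* local coordinates. Singleton components have
#' no defined orientation and get a zero rotation step.
#'
#' @param k Component index.
#' @param forces Matrix from [net_forces()] (rownames = vertex ids).
#' @param layouts List of local layouts.
#' @param placement A [component_placement()] (supplies the current angles).
#' @param config A [fragviz_config()] (supplies `step_c`, `step_phi`).
#' @return List with `dc` (length-2 translation) and `dphi` (radians).
#' @export
component_update <- function(k, forces, layouts, placement,
                             config = fragviz_config()) {
  V <- layouts[[k]]
  Fk <- forces[rownames(V), , drop = FALSE]
  dc <- config$step_c * colSums(Fk) / nrow(V)
  inertia <- sum(V^2)
  if (nrow(V) < 2 || inertia < .Machine$double.eps) {
    return(list(dc = dc, dphi = 0))
  }
  R <- rotate_coords(V, placement$angles[k])
  torque <- sum(R[, 1] * Fk[, 2] - R[, 2] * Fk[, 1])
  list(dc = dc, dphi = config$step_phi * torque / inertia)
}

#' Total layout stress
#'
#' Sum of squared spring residuals `(d_ij - ||g_i - g_j||)^2` over all
#' inter-component vertex pairs — the energy the placement engines minimize.
#'
#' @inheritParams net_forces
#' @return Nonnegative scalar.
#' @export
total_stress <- function(layouts, placement, D) {
  st <- stack_global(layouts, placement)
  G <- st$G
  Dm <- D[rownames(G), rownames(G), drop = FALSE]
  dx <- outer(G[, 1], G[, 1], "-")
  dy <- outer(G[, 2], G[, 2], "-")
  r <- sqrt(dx * dx + dy * dy)
  mask <- outer(st$comp, st$comp, "!=") & upper.tri(r)
  sum((Dm[mask] - r[mask])^2)
}

#' Exact semi-physical component placement
#'
#' Simulates the full spring system: starting from a seeded random placement
#' of component centers (angles zero), it repeatedly computes the net force
#' on every vertex and translates and rotates each rigid component by the
#' resulting step until the largest per-vertex force falls below
#' `config$force_tol` or `config$max_iterations` is reached. Infinite
#' friction is assumed: no momentum is retained between steps.
#'
#' @param layouts List of centered local layouts ([component_layouts()]).
#' @param D Dissimilarity matrix covering all vertices.
#' @param config A [fragviz_config()]; uses `step_c`, `step_phi`,
#'   `force_tol`, `max_iterations`.
#' @param seed Integer seed for the initial random centers.
#' @param init Optional [component_placement()] overriding the random start.
#' @return A list with `placement` (the final [component_placement()]),
#'   `trace` (tibble: iteration, max_force, total_stress) and `converged`.
#' @export
simulate_exact <- function(layouts, D, config = fragviz_config(), seed = 1,
                           init = NULL) {
  p <- length(layouts)
  if (p < 1) abort("at least one component required")
  if (is.null(init)) {
    side <- max(D, 1e-12)
    centers <- withr::with_seed(seed, matrix(runif(2 * p, 0, side), p, 2))
    placement <- component_placement(centers, rep(0, p), K = 1)
  } else {
    placement <- init
  }
  n_total <- sum(vapply(layouts, nrow, 1L))
  trace <- vector("list", config$max_iterations)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iterations)) {
    fs <- forces_and_stress(layouts, placement, D)
    F <- fs$forces
    if (!all(is.finite(F))) abort("step size too large")
    max_force <- if (nrow(F)) max(sqrt(rowSums(F^2))) else 0
    trace[[it]] <- c(
      iteration = it, max_force = max_force,
      total_stress = fs$stress
    )
    if (max_force < config$force_tol || p == 1) {
      converged <- TRUE
      break
    }
    for (k in seq_len(p)) {
      upd <- component_update(k, F, layouts, placement, config)
      # every vertex carries one spring per vertex outside its component, so
      # forces grow linearly with that count; dividing the step by it keeps
      # the explicit update stable independently of instance size
      n_other <- max(1L, n_total - nrow(layouts[[k]]))
      placement$centers[k, ] <- placement$centers[k, ] + upd$dc / n_other
      placement$angles[k] <- placement$angles[k] + upd$dphi / n_other
    }
    if (!all(is.finite(placement$centers))) abort("step size too large")
  }
  trace <- as_tibble(do.call(rbind, trace[seq_len(it)]))
  list(placement = placement, trace = trace, converged = converged)
}

#' Write an iteration trace to TSV
#'
#' @param trace Tibble with columns `iteration`, `max_force`, `total_stress`
#'   (from [simulate_exact()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.table(trace, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
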