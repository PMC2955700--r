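# Brute-force oracles, deliberately independent of the package internals:
# plain double loops over vertex pairs, scalar arithmetic only.

oracle_spring <- function(gi, gj, dij) {
  delta <- gi - gj
  r <- sqrt(sum(delta^2))
  (dij - r) * delta / r
}

# global positions as a named list of length-2 vectors
oracle_positions <- function(layouts, placement) {
  out <- list()
  for (k in seq_along(layouts)) {
    V <- layouts[[k]]
    phi <- placement$angles[k]
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    for (i in seq_len(nrow(V))) {
      out[[rownames(V)[i]]] <-
        as.numeric(R %*% V[i, ]) + placement$K * placement$centers[k, ]
    }
  }
  out
}

oracle_net_forces <- function(layouts, placement, D, intra = FALSE) {
  pos <- oracle_positions(layouts, placement)
  comp <- rep(seq_along(layouts), vapply(layouts, nrow, 1L))
  names(comp) <- unlist(lapply(layouts, rownames))
  ids <- names(pos)
  F <- matrix(0, length(ids), 2, dimnames = list(ids, NULL))
  for (i in ids) {
    for (j in ids) {
      if (i == j) next
      if (!intra && comp[i] == comp[j]) next
      F[i, ] <- F[i, ] + oracle_spring(pos[[i]], pos[[j]], D[i, j])
    }
  }
  F
}

oracle_total_stress <- function(layouts, placement, D) {
  pos <- oracle_positions(layouts, placement)
  comp <- rep(seq_along(layouts), vapply(layouts, nrow, 1L))
  names(comp) <- unlist(lapply(layouts, rownames))
  ids <- names(pos)
  s <- 0
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      i <- ids[a]
      j <- ids[b]
      if (comp[i] == comp[j]) next
      r <- sqrt(sum((pos[[i]] - pos[[j]])^2))
      s <- s + (D[i, j] - r)^2
    }
  }
  s
}

oracle_component_distances <- function(D, partition) {
  p <- length(partition)
  delta <- matrix(0, p, p)
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      if (k == l) next
      tot <- 0
      for (i in partition[[k]]) {
        for (j in partition[[l]]) tot <- tot + D[i, j]
      }
      delta[k, l] <- tot / (length(partition[[k]]) * length(partition[[l]]))
    }
  }
  delta
}

oracle_vbar <- function(layouts) {
  vals <- c()
  for (V in layouts) {
    n <- nrow(V)
    if (n < 2) next
    tot <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) tot <- tot + sqrt(sum((V[i, ] - V[j, ])^2))
      }
    }
    vals <- c(vals, tot / (n * (n - 1)))
  }
  mean(vals)
}

oracle_gbar <- function(centers) {
  p <- nrow(centers)
  tot <- 0
  for (k in seq_len(p - 1)) {
    for (l in (k + 1):p) tot <- tot + sqrt(sum((centers[k, ] - centers[l, ])^2))
  }
  2 * tot / (p * (p - 1))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (b > a && adj[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    cc[i] <- 2 * links / (length(nb) * (length(nb) - 1))
  }
  cc
}

# random multi-component test instance: centered random local layouts,
# random placement, random symmetric D
random_instance <- function(seed, p = 3, max_size = 5, scale = 2) {
  withr::with_seed(seed, {
    sizes <- sample(seq_len(max_size), p, replace = TRUE)
    ids <- sprintf("v%02d", seq_len(sum(sizes)))
    split_ids <- split(ids, rep(seq_len(p), sizes))
    layouts <- lapply(seq_len(p), function(k) {
      V <- matrix(runif(2 * sizes[k], -1, 1), sizes[k], 2)
      V <- sweep(V, 2, colMeans(V))
      rownames(V) <- split_ids[[k]]
      V
    })
    n <- sum(sizes)
    D <- matrix(runif(n * n, 0.5, scale), n, n, dimnames = list(ids, ids))
    D <- (D + t(D)) / 2
    diag(D) <- 0
    placement <- component_placement(
      centers = matrix(runif(2 * p, -scale, scale), p, 2),
      angles = runif(p, -pi, pi),
      K = runif(1, 0.5, 2)
    )
    list(layouts = layouts, placement = placement, D = D,
         partition = split_ids, sizes = sizes)
  })
}

# block instance family with heterogeneous block-level distances drawn at the
# scale of bounded functional-similarity scores (distances ~[0.5, 1])
score_scale_instance <- function(seed, p = 14) {
  env <- withr::with_seed(seed, {
    sizes <- sample(2:3, p, replace = TRUE)
    ctr <- matrix(runif(2 * p), p, 2)
    B <- as.matrix(dist(ctr))
    B <- 0.5 + 0.5 * B / max(B)
    diag(B) <- 0
    list(sizes = sizes, B = B)
  })
  block_dissimilarity(
    sizes = env$sizes, d_within = 0.3, d_between = env$B,
    jitter = 0.05, seed = seed
  )
}

make_rotation_instance <- function() {
  # one rotatable edge component between two singleton anchors; the target
  # rest lengths are satisfied only when the edge turns vertical (phi = pi/2)
  lays <- list(
    matrix(c(-1, 1, 0, 0), 2, 2, dimnames = list(c("p", "q"), NULL)),
    matrix(0, 1, 2, dimnames = list("u", NULL)),
    matrix(0, 1, 2, dimnames = list("w", NULL))
  )
  centers <- rbind(c(0, 0), c(0, 3), c(0, -3))
  ids <- c("p", "q", "u", "w")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["p", "u"] <- D["u", "p"] <- 2
  D["q", "u"] <- D["u", "q"] <- 4
  D["p", "w"] <- D["w", "p"] <- 4
  D["q", "w"] <- D["w", "q"] <- 2
  D["u", "w"] <- D["w", "u"] <- 6
  list(lays = lays, centers = centers, D = D)
}

rotation_stress <- function(inst, phi) {
  pl <- component_placement(inst$centers, c(phi, 0, 0), 1)
  total_stress(inst$lays, pl, inst$D)
}

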