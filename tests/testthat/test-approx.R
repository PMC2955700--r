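test_that("component distances are average-linkage distances", {
  ids <- c("a", "b", "c")
  D <- matrix(c(0, 1, 7, 1, 0, 7, 7, 7, 0), 3, dimnames = list(ids, ids))
  part <- list(c("a", "b"), "c")
  delta <- component_distances(D, part)
  expect_equal(delta[1, 2], 7)
  expect_equal(diag(delta), c("1" = 0, "2" = 0))

  D <- matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3, dimnames = list(ids, ids))
  expect_equal(component_distances(D, list(c("a", "b"), "c"))[1, 2], 3)

  # random partitions against the nested-loop oracle
  for (seed in 1:5) {
    n <- 40
    ids <- sprintf("v%02d", 1:n)
    D <- withr::with_seed(seed, {
      m <- matrix(runif(n * n), n, n)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    })
    dimnames(D) <- list(ids, ids)
    part <- split(ids, withr::with_seed(seed + 1, sample(1:6, n, replace = TRUE)))
    expect_equal(
      unname(component_distances(D, part)),
      oracle_component_distances(D, part),
      tolerance = 1e-12
    )
  }
})

test_that("component distances agree with hclust average linkage", {
  # for a 2-block instance the final average-linkage merge height is exactly
  # the average-linkage distance between the two components
  inst <- block_dissimilarity(sizes = c(4, 3), d_within = 1, d_between = 5,
                              jitter = 0.4, seed = 3)
  part <- find_components(inst$network)
  delta <- component_distances(inst$D, part)
  hc <- stats::hclust(stats::as.dist(inst$D), method = "average")
  expect_equal(delta[1, 2], max(hc$height), tolerance = 1e-12)
})

test_that("SMACOF embeds exactly realizable distances and never diverges", {
  # two points are always realizable
  fit <- smacof_mds(matrix(c(0, 4, 4, 0), 2), seed = 1)
  expect_equal(as.numeric(dist(fit$conf)), 4, tolerance = 1e-6)

  # planar point sets re-embed to (nearly) zero stress
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, matrix(runif(10, 0, 3), 5, 2))
    delta <- as.matrix(dist(pts))
    fit <- smacof_mds(delta, seed = seed, init_method = "torgerson")
    expect_lt(fit$stress, 1e-6)
    expect_equal(as.matrix(dist(fit$conf)), delta, tolerance = 1e-3)
  }

  # strongly non-metric input terminates with positive stress
  bad <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3)
  fit <- smacof_mds(bad, seed = 2)
  expect_gt(fit$stress, 0)
  expect_true(all(is.finite(fit$conf)))

  # single point sits at the origin
  expect_equal(smacof_mds(matrix(0, 1, 1))$conf, matrix(0, 1, 2))
})

test_that("SMACOF stress is non-increasing at every iteration", {
  for (seed in 1:20) {
    delta <- withr::with_seed(seed, {
      m <- matrix(runif(64, 0.2, 3), 8, 8)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    })
    fit <- smacof_mds(delta, seed = seed)
    expect_true(all(diff(fit$trace) <= 1e-12))
  }
})

test_that("SMACOF agrees with classical scaling on Euclidean input", {
  pts <- withr::with_seed(9, matrix(rnorm(16), 8, 2))
  delta <- as.matrix(dist(pts))
  fit <- smacof_mds(delta, seed = 9, init_method = "torgerson")
  cs <- cmdscale(delta, k = 2)
  expect_equal(as.matrix(dist(fit$conf)), as.matrix(dist(cs)),
    tolerance = 1e-4, ignore_attr = TRUE
  )
})

test_that("the scaling factor is the size-to-spread ratio", {
  edge <- matrix(c(-1, 1, 0, 0), 2, 2)
  lays <- list(edge, edge)
  rownames(lays[[1]]) <- c("a", "b")
  rownames(lays[[2]]) <- c("c", "d")
  centers <- rbind(c(0, 0), c(4, 0))
  expect_equal(scaling_factor(lays, centers), 0.5) # v_bar 2, g_bar 4

  # all singletons: declared degenerate, K defaults to 1
  sing <- lapply(c("a", "b"), function(i) matrix(0, 1, 2, dimnames = list(i, NULL)))
  expect_warning(K <- scaling_factor(sing, centers), class = "fragnet_scale_default")
  expect_equal(K, 1)
  expect_warning(scaling_factor(lays[1], centers[1, , drop = FALSE]),
    class = "fragnet_scale_default"
  )
  expect_error(
    scaling_factor(lays, rbind(c(1, 1), c(1, 1))),
    "degenerate MDS solution"
  )

  # random instances against the double-loop sums
  for (seed in 1:5) {
    inst <- random_instance(seed, p = 4)
    if (all(inst$sizes < 2)) next
    K <- scaling_factor(inst$layouts, inst$placement$centers)
    expect_equal(
      K,
      oracle_vbar(inst$layouts) / oracle_gbar(inst$placement$centers),
      tolerance = 1e-12
    )
  }
})

test_that("rotation annealing leaves singletons alone and lowers stress", {
  # all singletons: nothing to rotate
  ids <- c("a", "b", "c")
  lays <- lapply(ids, function(i) matrix(0, 1, 2, dimnames = list(i, NULL)))
  D <- matrix(2, 3, 3, dimnames = list(ids, ids))
  diag(D) <- 0
  centers <- rbind(c(0, 0), c(2, 0), c(1, 2))
  rot <- optimize_rotations(lays, centers, 1, D)
  expect_equal(rot$angles, c(0, 0, 0))
  expect_equal(rot$trace$stress, rep(rot$trace$stress[1], nrow(rot$trace)))
})

test_that("greedy rotation finds the grid-search optimum angle", {
  inst <- make_rotation_instance()
  grid <- seq(-pi, pi, length.out = 2001)
  curve <- vapply(grid, function(a) rotation_stress(inst, a), 1)
  best <- grid[which.min(curve)]
  rot <- optimize_rotations(
    inst$lays, inst$centers, 1, inst$D,
    schedule = anneal_schedule(t0 = 0, sweeps = 400, seed = 4),
    config = fragviz_config(step_phi = 0.5)
  )
  # angle modulo 2*pi, compared on the circle
  diff_angle <- abs(atan2(sin(rot$angles[1] - best), cos(rot$angles[1] - best)))
  expect_lt(diff_angle, 0.1)
  expect_lt(rot$trace$stress[nrow(rot$trace)], rot$trace$stress[1])
})

test_that("zero-temperature rotation never raises the stress", {
  for (seed in 1:3) {
    inst <- random_instance(seed, p = 4)
    rot <- optimize_rotations(
      inst$layouts, inst$placement$centers, 1, inst$D,
      schedule = anneal_schedule(t0 = 0, sweeps = 20, seed = seed)
    )
    expect_true(all(diff(rot$trace$stress) <= 1e-12))
  }
})

test_that("the rotation phase is rigid: shapes and centers unchanged", {
  inst <- score_scale_instance(3, p = 8)
  lay <- fragviz_layout(inst$network, inst$D, seed = 2)
  part <- find_components(inst$network)
  m <- cbind(lay$x, lay$y)
  rownames(m) <- lay$vertex
  lays <- component_layouts(inst$network, part, 500, 2)
  for (k in seq_along(part)) {
    if (length(part[[k]]) < 2) next
    expect_equal(
      as.numeric(dist(m[part[[k]], ])),
      as.numeric(dist(lays[[k]])),
      tolerance = 1e-9
    )
  }
})
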