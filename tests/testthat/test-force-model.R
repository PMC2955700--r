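test_that("global positions compose rotation, translation and scaling", {
  expect_equal(global_position(c(1, 0), 0, c(2, 3), 1), c(3, 3))
  expect_equal(global_position(c(1, 0), pi / 2, c(0, 0), 1), c(0, 1),
    tolerance = 1e-12
  )
  expect_equal(global_position(c(1, 1), 0, c(2, 2), 3), c(7, 7))
})

test_that("spring forces follow Hooke's law with rest length d", {
  expect_equal(spring_force(c(0, 0), c(1, 0), 1), c(0, 0))
  # stretched spring pulls i toward j
  expect_equal(spring_force(c(0, 0), c(3, 0), 1), c(2, 0))
  # antisymmetry on random instances
  for (seed in 1:100) {
    z <- withr::with_seed(seed, runif(5, -3, 3))
    gi <- z[1:2]
    gj <- z[3:4]
    d <- abs(z[5])
    expect_equal(spring_force(gi, gj, d), -spring_force(gj, gi, d),
      tolerance = 1e-12
    )
  }
  # coincident points: warned, magnitude equals the rest length
  expect_warning(
    f <- spring_force(c(1, 1), c(1, 1), 2.5),
    class = "fragnet_coincident"
  )
  expect_equal(sqrt(sum(f^2)), 2.5, tolerance = 1e-12)
})

test_that("net forces vanish at exactly-realized configurations", {
  lay1 <- matrix(0, 1, 2, dimnames = list("a", NULL))
  lay2 <- matrix(0, 1, 2, dimnames = list("b", NULL))
  D <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pl <- component_placement(rbind(c(0, 0), c(4, 0)), c(0, 0), 1)
  F <- net_forces(list(lay1, lay2), pl, D)
  expect_equal(max(abs(F)), 0, tolerance = 1e-12)

  # unit square of singletons with side/diagonal rest lengths
  ids <- c("a", "b", "c", "d")
  lays <- lapply(ids, function(i) matrix(0, 1, 2, dimnames = list(i, NULL)))
  ctr <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(ctr))
  dimnames(D) <- list(ids, ids)
  pl <- component_placement(ctr, rep(0, 4), 1)
  expect_equal(max(abs(net_forces(lays, pl, D))), 0, tolerance = 1e-12)
})

test_that("net forces match the brute-force pairwise oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed, p = 3)
    F <- net_forces(inst$layouts, inst$placement, inst$D)
    Fo <- oracle_net_forces(inst$layouts, inst$placement, inst$D)
    expect_equal(F[rownames(Fo), ], Fo, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("component updates convert force to translation and torque", {
  cfg1 <- fragviz_config(step_c = 1, step_phi = 1)
  # all-zero forces: fixed point
  inst <- random_instance(1, p = 2)
  F0 <- matrix(0, sum(inst$sizes), 2,
    dimnames = list(unlist(lapply(inst$layouts, rownames)), NULL)
  )
  upd <- component_update(1, F0, inst$layouts, inst$placement, cfg1)
  expect_equal(upd$dc, c(0, 0), ignore_attr = TRUE)
  expect_equal(upd$dphi, 0)

  # singleton under force (2, 0): translation only
  lays <- list(
    matrix(0, 1, 2, dimnames = list("s", NULL)),
    matrix(c(-1, 1, 0, 0), 2, 2, dimnames = list(c("p", "q"), NULL))
  )
  pl <- component_placement(rbind(c(0, 0), c(5, 0)), c(0, 0), 1)
  F <- rbind(s = c(2, 0), p = c(0, 0), q = c(0, 0))
  upd <- component_update(1, F, lays, pl, cfg1)
  expect_equal(upd$dc, c(2, 0), ignore_attr = TRUE)
  expect_equal(upd$dphi, 0)

  # two-vertex component at (+-1, 0), tangential force couple: 1 rad
  F <- rbind(s = c(0, 0), p = c(0, -1), q = c(0, 1))
  upd <- component_update(2, F, lays, pl, cfg1)
  expect_equal(upd$dc, c(0, 0), ignore_attr = TRUE)
  expect_equal(upd$dphi, (1 * 1 + 1 * 1) / 2)
})

test_that("including intra-component pairs changes no rigid-body update", {
  cfg <- fragviz_config()
  for (seed in 1:20) {
    inst <- random_instance(seed, p = 3)
    F_inter <- net_forces(inst$layouts, inst$placement, inst$D, intra = FALSE)
    F_all <- net_forces(inst$layouts, inst$placement, inst$D, intra = TRUE)
    for (k in seq_along(inst$layouts)) {
      u1 <- component_update(k, F_inter, inst$layouts, inst$placement, cfg)
      u2 <- component_update(k, F_all, inst$layouts, inst$placement, cfg)
      expect_equal(u1$dc, u2$dc, tolerance = 1e-9)
      expect_equal(u1$dphi, u2$dphi, tolerance = 1e-9)
    }
  }
})

test_that("forces and updates are invariant under global translation", {
  inst <- random_instance(5, p = 4)
  shifted <- inst$placement
  shifted$centers <- sweep(shifted$centers, 2, c(-3.2, 7.9), "+")
  F1 <- net_forces(inst$layouts, inst$placement, inst$D)
  F2 <- net_forces(inst$layouts, shifted, inst$D)
  expect_equal(F1, F2, tolerance = 1e-9)
})

test_that("total stress sums squared inter-component residuals", {
  lay1 <- matrix(0, 1, 2, dimnames = list("a", NULL))
  lay2 <- matrix(0, 1, 2, dimnames = list("b", NULL))
  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  # exact realization: zero stress
  pl <- component_placement(rbind(c(0, 0), c(2, 0)), c(0, 0), 1)
  expect_equal(total_stress(list(lay1, lay2), pl, D), 0)
  # placed at distance 1 with rest length 2: (2 - 1)^2
  pl <- component_placement(rbind(c(0, 0), c(1, 0)), c(0, 0), 1)
  expect_equal(total_stress(list(lay1, lay2), pl, D), 1)

  for (seed in 1:10) {
    inst <- random_instance(seed, p = 4)
    expect_equal(
      total_stress(inst$layouts, inst$placement, inst$D),
      oracle_total_stress(inst$layouts, inst$placement, inst$D),
      tolerance = 1e-10
    )
  }
})

test_that("the exact simulation reaches closed-form equilibria", {
  lays <- list(
    matrix(0, 1, 2, dimnames = list("a", NULL)),
    matrix(0, 1, 2, dimnames = list("b", NULL))
  )
  D <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- simulate_exact(lays, D, seed = 11)
  expect_true(sim$converged)
  gap <- sqrt(sum((sim$placement$centers[1, ] - sim$placement$centers[2, ])^2))
  expect_equal(gap, 5, tolerance = 1e-3)

  # a 3-4-5 triangle is exactly realizable in the plane
  ids <- c("a", "b", "c")
  lays <- lapply(ids, function(i) matrix(0, 1, 2, dimnames = list(i, NULL)))
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(ids, ids))
  sim <- simulate_exact(lays, D, seed = 2)
  got <- as.matrix(dist(sim$placement$centers))
  expect_equal(got[1, 2], 3, tolerance = 1e-2)
  expect_equal(got[1, 3], 4, tolerance = 1e-2)
  expect_equal(got[2, 3], 5, tolerance = 1e-2)
})

test_that("zero-force configurations are fixed points of the simulation", {
  lays <- list(
    matrix(0, 1, 2, dimnames = list("a", NULL)),
    matrix(0, 1, 2, dimnames = list("b", NULL))
  )
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  init <- component_placement(rbind(c(1, 1), c(4, 1)), c(0, 0), 1)
  sim <- simulate_exact(lays, D, seed = 1, init = init)
  expect_true(sim$converged)
  expect_equal(sim$placement$centers, init$centers)
  expect_equal(nrow(sim$trace), 1) # converged on the first force check
})

test_that("a single component feels no forces and keeps its placement", {
  lay <- matrix(c(-1, 1, 0, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  init <- component_placement(matrix(c(3, 4), 1, 2), 0.7, 1)
  sim <- simulate_exact(list(lay), D, seed = 9, init = init)
  expect_true(sim$converged)
  expect_equal(sim$placement$centers, init$centers)
  expect_equal(sim$placement$angles, init$angles)
})

test_that("stress is non-increasing under small simulation steps", {
  cfg <- fragviz_config(step_c = 0.02, step_phi = 0.02, max_iterations = 300)
  for (seed in 1:3) {
    inst <- random_instance(seed, p = 5)
    sim <- simulate_exact(inst$layouts, inst$D, cfg, seed = seed)
    expect_true(all(diff(sim$trace$total_stress) <= 1e-9))
  }
})
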