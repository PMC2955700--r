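test_that("connected components are found and ordered deterministically", {
  # edgeless graph: every vertex its own component
  g <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g)$name <- letters[1:5]
  blocks <- find_components(g)
  expect_length(blocks, 5)
  expect_equal(unlist(blocks), letters[1:5])

  # a path is a single component
  path <- network_from_edges(data.frame(x = c("a", "b", "c"), y = c("b", "c", "d")))
  expect_equal(find_components(path), structure(list(c("a", "b", "c", "d")),
    class = "component_partition"
  ))

  # two disjoint triangles
  tri2 <- network_from_edges(data.frame(
    x = c("a", "b", "c", "p", "q", "r"),
    y = c("b", "c", "a", "q", "r", "p")
  ))
  expect_equal(lengths(find_components(tri2)), c(3L, 3L))

  expect_error(
    find_components(igraph::make_empty_graph(0, directed = FALSE)),
    "empty graph"
  )
})

test_that("component detection is invariant to vertex relabeling", {
  for (seed in 1:5) {
    g <- withr::with_seed(seed, igraph::sample_gnp(15, 0.08))
    igraph::V(g)$name <- sprintf("v%02d", 1:15)
    blocks <- find_components(g)
    perm <- withr::with_seed(seed + 100, sample(15))
    g2 <- igraph::permute(g, perm)
    blocks2 <- find_components(g2)
    # same partition as a set of sets
    canon <- function(b) sort(vapply(b, function(x) paste(sort(x), collapse = ","), ""))
    expect_equal(canon(blocks2), canon(blocks))
    # idempotence: recomputation is identical
    expect_identical(find_components(g), blocks)
  }
})

test_that("threshold networks follow the strict edge rule", {
  s <- matrix(c(1, .9, .5, .9, 1, .5, .5, .5, 1), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  net <- threshold_network(s, 0.7, keep_isolated = FALSE)
  expect_setequal(igraph::V(net)$name, c("a", "b"))
  expect_equal(igraph::ecount(net), 1)

  # threshold above every off-diagonal similarity: edgeless but all kept
  hi <- threshold_network(s, 0.95, keep_isolated = TRUE)
  expect_equal(igraph::vcount(hi), 3)
  expect_equal(igraph::ecount(hi), 0)

  # threshold below every similarity: complete graph
  lo <- threshold_network(s, 0.4, keep_isolated = TRUE)
  expect_equal(igraph::ecount(lo), 3)

  # strictly-exceeds: a score equal to the threshold is not an edge
  expect_equal(igraph::ecount(threshold_network(s, 0.9, keep_isolated = TRUE)), 0)

  s2 <- s
  s2[1, 2] <- 0.3
  expect_error(threshold_network(s2, 0.5), "not symmetric")
})

test_that("raising the threshold never merges components", {
  for (seed in 1:5) {
    s <- withr::with_seed(seed, {
      m <- matrix(runif(100), 10, 10)
      (m + t(m)) / 2
    })
    dimnames(s) <- list(letters[1:10], letters[1:10])
    diag(s) <- 1
    ncomp <- vapply(seq(0, 1, by = 0.1), function(th) {
      length(find_components(threshold_network(s, th, keep_isolated = TRUE)))
    }, 1L)
    expect_true(all(diff(ncomp) >= 0))
  }
})

test_that("local clustering coefficients match the neighbor-clique definition", {
  tri <- network_from_edges(data.frame(x = c("a", "b", "c"), y = c("b", "c", "a")))
  cc <- local_clustering_coefficient(tri)
  expect_equal(cc$coefficient, rep(1, 3))
  expect_equal(average_clustering_coefficient(tri), 1)

  star <- network_from_edges(data.frame(x = rep("h", 4), y = paste0("l", 1:4)))
  cc <- local_clustering_coefficient(star)
  expect_equal(cc$coefficient[cc$vertex == "h"], 0)
  expect_true(all(is.na(cc$coefficient[cc$vertex != "h"]))) # degree 1
  expect_equal(average_clustering_coefficient(star), 0)

  # random graphs against the brute-force triangle-counting oracle
  for (seed in 1:5) {
    g <- withr::with_seed(seed, igraph::sample_gnp(20, 0.25))
    igraph::V(g)$name <- sprintf("v%02d", 1:20)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    got <- local_clustering_coefficient(g)$coefficient
    expect_equal(got, oracle_clustering(adj), tolerance = 1e-12)
    expect_true(all(got[!is.na(got)] >= 0 & got[!is.na(got)] <= 1))
  }

  # complete graph scores exactly 1
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  expect_identical(average_clustering_coefficient(k6), 1)
})

test_that("similarity converts to dissimilarity by min-max complement", {
  s <- matrix(c(1, 1, 0, 1, 1, 0.5, 0, 0.5, 1), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  d <- dissimilarity_from_similarity(s, mode = "one_minus")
  expect_equal(d["a", "b"], 0) # maximal similarity
  expect_equal(d["a", "c"], 1) # minimal similarity
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  # identity mode validates and passes through
  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_identical(dissimilarity_from_similarity(D, mode = "identity"), D)

  expect_error(
    dissimilarity_from_similarity(matrix(1, 3, 3), mode = "one_minus"),
    "degenerate similarity"
  )
})
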