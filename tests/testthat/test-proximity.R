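test_that("epsilon-zero walk converges to the lazy-walk stationary distribution", {
  cfg <- walk_config(epsilon = 0, convergence = 1e-9, max_iterations = 10000)
  # K2 and path worked examples
  k2 <- path_graph("a", "b")
  expect_equal(unname(random_walk_row(k2, "a", cfg)), c(0.5, 0.5), tolerance = 1e-6)
  p3 <- path_graph("A", "B", "C")
  expect_equal(unname(random_walk_row(p3, "A", cfg)), c(2, 3, 2) / 7, tolerance = 1e-6)

  # pi(v) proportional to deg(v) + 1 on 50 random connected graphs
  withr::local_seed(101)
  for (rep in 1:50) {
    g <- random_test_graph(sample(3:9, 1), stats::runif(1, 0.35, 0.8), connected = TRUE)
    deg <- igraph::degree(g)
    expected <- (deg + 1) / sum(deg + 1)
    row <- random_walk_row(g, igraph::V(g)$name[1], cfg)
    expect_lt(sum(abs(row - expected)), 1e-6)
  }
})

test_that("walk rows stay probability vectors and single nodes are absorbing", {
  solo <- igraph::add_vertices(igraph::make_empty_graph(0, directed = FALSE),
                               1, name = "x")
  expect_equal(random_walk_row(solo, "x"), c(x = 1))

  withr::local_seed(55)
  for (rep in 1:20) {
    g <- random_test_graph(6, 0.5)
    P <- random_walk_matrix(g, walk_config(epsilon = 1e-4, max_iterations = 40))
    expect_equal(unname(rowSums(P)), rep(1, igraph::vcount(g)), tolerance = 1e-9)
    expect_true(all(P >= 0))
  }
})

test_that("an over-large epsilon raises a numeric error naming epsilon", {
  g <- path_graph("a", "b", "c")
  expect_error(random_walk_row(g, "a", walk_config(epsilon = 10)), "epsilon")
})

test_that("distance matrices match a BFS oracle, are symmetric and metric per component", {
  p3 <- path_graph("A", "B", "C")
  D <- distance_matrix(p3)
  expect_equal(D["A", "C"], 2)
  expect_equal(unname(diag(D)), rep(0, 3))

  two <- igraph::make_graph(~ a - b, c - d)
  D2 <- distance_matrix(two)
  expect_equal(D2["a", "c"], 0)           # zero sentinel across components
  D2n <- distance_matrix(two, sentinel = "nv")
  expect_equal(D2n["a", "c"], 4)          # |V| sentinel mode

  withr::local_seed(77)
  for (rep in 1:25) {
    g <- random_test_graph(sample(5:30, 1), 0.15)
    D <- distance_matrix(g)
    O <- oracle_distances(g)
    O[is.infinite(O)] <- 0
    expect_equal(D[rownames(O), colnames(O)], O)
    expect_equal(D, t(D))
    # triangle inequality within components (finite oracle entries)
    Of <- oracle_distances(g)
    nm <- rownames(Of)
    for (k in 1:10) {
      uvw <- sample(nm, 3)
      duv <- Of[uvw[1], uvw[2]]; duw <- Of[uvw[1], uvw[3]]; dwv <- Of[uvw[3], uvw[2]]
      if (is.finite(duw) && is.finite(dwv)) expect_lte(duv, duw + dwv)
    }
  }
})

test_that("pcc returns the exact correlation with a defined constant-vector fallback", {
  x <- c(0, 1, 2)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(c(1, 1, 1), x), 0)
  expect_error(pcc(1:3, 1:4), "length")
})

test_that("column-correlation measures hit pair_count on identity pairs and rank ascending", {
  H <- path_graph("A", "B", "C", "D")
  iset <- build_instance_set(H, identity_instances(H, 3))
  for (kind in c("random_walk", "distance")) {
    m <- column_correlation_measure(iset, kind)
    expect_equal(m$direction, "ascending")
    expect_equal(unname(m$weights[igraph::V(H)$name]),
                 rep(3, 4), tolerance = 1e-6)
  }
})

test_that("genes absent from both graphs of a pair contribute the zero fallback", {
  H <- path_graph("A", "B", "C", "D")
  i1 <- sample_instance("p1", c("A", "B", "C"), c("A", "B", "C"))  # D absent twice
  i2 <- sample_instance("p2", c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  m <- column_correlation_measure(build_instance_set(H, list(i1, i2)), "distance")
  expect_equal(unname(m$weights["D"]), 1, tolerance = 1e-9)  # 0 from pair 1, 1 from pair 2
})

test_that("jaccard measures implement the formula with the empty-union convention", {
  # Ne_N(v) = {a,b}, Ne_T(v) = {b,c} -> 1/3
  H <- star_graph("v", c("a", "b", "c"))
  i <- sample_instance("p", c("v", "a", "b"), c("v", "b", "c"))
  m <- jaccard_measure(build_instance_set(H, list(i)), 1L)
  expect_equal(unname(m$weights["v"]), 1 / 3)

  # v present in normal only with degree >= 1 -> 0 for that pair
  i2 <- sample_instance("q", c("v", "a"), c("a"))
  m2 <- jaccard_measure(build_instance_set(H, list(i2)), 1L)
  expect_equal(unname(m2$weights["v"]), 0)

  # identical neighborhoods across r pairs -> weight r, and bounds hold
  iset <- build_instance_set(H, identity_instances(H, 5))
  for (ord in 1:2) {
    m3 <- jaccard_measure(iset, ord)
    expect_equal(unname(m3$weights), rep(5, 4))
    expect_true(all(m3$weights >= 0 & m3$weights <= iset$pair_count))
  }
})

test_that("perturbing a gene's tumor neighborhood strictly lowers its first-order jaccard weight", {
  withr::local_seed(13)
  H <- random_test_graph(10, 0.4, connected = TRUE)
  genes <- igraph::V(H)$name
  target <- genes[which.max(igraph::degree(H))]
  base <- lapply(1:3, function(i) sample_instance(paste0("b", i), genes, genes))
  drop1 <- igraph::neighbors(H, target)$name[1]
  pert <- c(base[1:2],
            list(sample_instance("p3", genes, setdiff(genes, drop1))))
  w_base <- jaccard_measure(build_instance_set(H, base), 1L)$weights[target]
  w_pert <- jaccard_measure(build_instance_set(H, pert), 1L)$weights[target]
  expect_lt(w_pert, w_base)
})
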