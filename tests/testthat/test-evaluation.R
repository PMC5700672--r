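test_that("top_fraction uses the ceiling rule", {
  genes <- paste0("g", 1:250)
  expect_equal(top_fraction(genes, 100), genes)
  expect_length(top_fraction(genes, 1), 3L)      # ceil(2.5)
  expect_length(top_fraction(paste0("g", 1:100), 7), 7L)
})

test_that("roc/pr sweeps match the confusion-matrix oracle and worked AUROC values", {
  # perfect ranking
  perfect <- roc_pr_sweep(paste0("g", 1:10), paste0("g", 1:3))
  expect_equal(perfect$auroc, 1)

  # hand-worked 4-gene example at rank resolution
  cv <- roc_pr_sweep(c("g1", "g2", "g3", "g4"), c("g1", "g3"), resolution = "rank")
  expect_equal(cv$auroc, 0.75)

  # oracle agreement on random small instances
  withr::local_seed(31)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    universe <- paste0("g", seq_len(n))
    ranking <- sample(universe)
    gold <- sample(universe, sample(1:(n - 1), 1))
    cv <- roc_pr_sweep(ranking, gold, universe, resolution = "rank")
    for (s in seq_len(n)) {
      o <- oracle_confusion(ranking, gold, universe, s)
      row <- cv$points[cv$points$size == s, ]
      expect_equal(row$tp, unname(o["tp"]))
      expect_equal(row$tpr, unname(o["tpr"]))
      expect_equal(row$fpr, unname(o["fpr"]))
      expect_equal(row$precision, unname(o["precision"]))
    }
  }
})

test_that("random rankings score near 0.5 and reversal AUROCs sum to about 1", {
  withr::local_seed(99)
  universe <- paste0("g", 1:400)
  gold <- sample(universe, 40)
  aurocs <- replicate(30, roc_pr_sweep(sample(universe), gold, universe)$auroc)
  expect_equal(mean(aurocs), 0.5, tolerance = 0.05)

  ranking <- sample(universe)
  a1 <- roc_pr_sweep(ranking, gold, universe, resolution = "rank")$auroc
  a2 <- roc_pr_sweep(rev(ranking), gold, universe, resolution = "rank")$auroc
  expect_equal(a1 + a2, 1, tolerance = 0.02)
})

test_that("empty gold standards after restriction are rejected", {
  expect_error(roc_pr_sweep(c("a", "b"), "z"), "empty")
})

# toy ontology: root L0; chain c1(L1)..c4(L4); five(L5) under c4; six(L6)
# under five; seven(L7) under six; shallow(L3) under c2; a second L5 term
toy_level_annotation <- function() {
  edges <- c("c1", "root", "c2", "c1", "c3", "c2", "c4", "c3",
             "five", "c4", "fiveB", "c4", "six", "five", "six", "fiveB",
             "seven", "six", "shallow", "c2")
  ont <- igraph::make_graph(edges, directed = TRUE)
  go_annotation(list(gA = "five", gB = "shallow", gC = "seven", gD = "fiveB"),
                ont)
}

test_that("level restriction keeps, drops, and lifts annotations as specified", {
  ann5 <- restrict_go_level(toy_level_annotation(), 5)
  expect_equal(ann5$annotations$gA, "five")                 # at level: kept
  expect_length(ann5$annotations$gB, 0L)                    # shallower: dropped
  expect_setequal(ann5$annotations$gC, c("five", "fiveB"))  # deeper: both L5 ancestors
  expect_equal(ann5$annotations$gD, "fiveB")
})

test_that("goc matches worked values and is linear in the test list", {
  ont <- igraph::make_graph(c("t1", "r", "t2", "r", "t3", "r"), directed = TRUE)
  ident <- go_annotation(list(a = c("t1", "t2"), b = c("t1", "t2"),
                              c = c("t1", "t2")), ont)
  # annotation-identical lists: GOC = |test|
  expect_equal(goc_score(c("a", "b"), c("b", "c"), ident), 2)
  # disjoint annotations: 0
  disj <- go_annotation(list(a = "t1", b = "t2"), ont)
  expect_equal(goc_score("a", "b", disj), 0)
  # three-gene worked example: (1/2 + 1/3) / 2 = 5/12
  wk <- go_annotation(list(t = c("t1", "t2"), r1 = "t1", r2 = c("t2", "t3")), ont)
  expect_equal(goc_score("t", c("r1", "r2"), wk), 5 / 12)
  expect_error(goc_score("a", character(0), ident), "empty")

  # linearity: GOC(T1 u T2) = GOC(T1) + GOC(T2) for disjoint test lists
  withr::local_seed(3)
  genes <- paste0("g", 1:12)
  pool <- paste0("t", 1:3)
  ann <- go_annotation(stats::setNames(lapply(genes, function(g) {
    sample(pool, sample(1:2, 1))
  }), genes), ont)
  t1 <- genes[1:4]; t2 <- genes[5:8]; ref <- genes[9:12]
  expect_equal(goc_score(c(t1, t2), ref, ann),
               goc_score(t1, ref, ann) + goc_score(t2, ref, ann))
})

test_that("rewiring preserves nodes and edge count, is seeded, and respects adjacency rules", {
  withr::local_seed(7)
  g <- random_test_graph(30, 0.15)
  expect_identical(rewire_network(g, 0), g)

  r1 <- rewire_network(g, 20, seed = 5)
  r2 <- rewire_network(g, 20, seed = 5)
  canon <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(canon(r1), canon(r2))                 # deterministic under seed
  expect_setequal(igraph::V(r1)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(r1), igraph::ecount(g))
  expect_true(igraph::is_simple(r1))
  # inserted edges were non-adjacent in the original network
  new_edges <- setdiff(canon(r1), canon(g))
  expect_length(new_edges, round(0.2 * igraph::ecount(g)))
  for (e in new_edges) {
    uv <- strsplit(e, " ")[[1]]
    expect_false(igraph::are_adjacent(g, uv[1], uv[2]))
  }

  # infeasible: K4 has no non-adjacent pairs
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_error(rewire_network(k4, 50, seed = 1), "infeasible")
})

test_that("a zero-ratio rewiring experiment reproduces the unrewired evaluation", {
  withr::local_seed(21)
  H <- random_test_graph(25, 0.2)
  genes <- igraph::V(H)$name
  insts <- lapply(1:4, function(i) {
    sample_instance(paste0("p", i), genes, sample(genes, 20))
  })
  gold <- sample(genes, 5)
  res <- suppressMessages(
    rewiring_experiment(H, insts, "deg1", gold,
                        rewire_config(ratios = 5, replicates = 2, seed = 3)))
  base <- res$table[res$table$ratio == 0, ]
  fit <- diffcent(H, insts, measures = "deg1")
  cv <- roc_pr_sweep(ranked_genes(fit$results$deg1), gold,
                     fit$instance_set$universe)
  expect_equal(base$mean_auroc, cv$auroc)
  expect_equal(base$mean_aupr, cv$aupr)
  expect_equal(res$graphs_built, 2L * 4L * 1L * 2L)
})
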