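small_cfg <- function(...) {
  synthetic_config(n_genes = 120L, n_instances = 10L, n_drivers = 6L, seed = 7L, ...)
}

test_that("the network generator is seeded, connected, and heavy-tailed", {
  cfg <- small_cfg()
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_equal(igraph::vcount(g1), 120L)
  expect_true(igraph::is_connected(g1))
  expect_true(igraph::is_simple(g1))

  # heavier tail than a density-matched Erdos-Renyi control
  withr::local_seed(1)
  m <- igraph::ecount(g1)
  er_max <- replicate(20, {
    er <- igraph::sample_gnm(igraph::vcount(g1), m)
    max(igraph::degree(er))
  })
  expect_gt(max(igraph::degree(g1)), mean(er_max))
})

test_that("instance generation is deterministic and plants drivers as configured", {
  cfg <- small_cfg()
  H <- generate_network(cfg)
  a <- generate_instances(cfg, H)
  b <- generate_instances(cfg, H)
  expect_identical(a, b)
  expect_length(a$instances, 10L)
  expect_length(a$gold, 6L)
  # drivers are the highest-degree genes, ties broken lexicographically
  deg <- igraph::degree(H)
  expected <- igraph::V(H)$name[order(-deg, igraph::V(H)$name,
                                      method = "radix")][1:6]
  expect_equal(a$gold, expected)

  # degenerate config: no perturbation at all -> N_i = T_i everywhere
  cfg0 <- synthetic_config(n_genes = 60L, n_instances = 4L, n_drivers = 3L,
                           driver_dropout = 0, background_flip = 0,
                           mutation_rate = 0, seed = 2L)
  H0 <- generate_network(cfg0)
  gi0 <- generate_instances(cfg0, H0)
  for (inst in gi0$instances) {
    expect_setequal(inst$normal_expressed, inst$tumor_expressed)
    expect_length(inst$tumor_mutated, 0L)
  }
  iset0 <- build_instance_set(H0, gi0$instances)
  expect_true(all(differential_sum(iset0, degree_order1)$weights == 0))

  # full dropout in driver mode removes every driver from every tumor set
  cfg1 <- synthetic_config(n_genes = 60L, n_instances = 4L, n_drivers = 3L,
                           driver_dropout = 1, background_flip = 0,
                           driver_removal = "driver", seed = 2L)
  gi1 <- generate_instances(cfg1, generate_network(cfg1))
  for (inst in gi1$instances) {
    expect_length(intersect(gi1$gold, inst$tumor_expressed), 0L)
  }
})

test_that("with clean background and driver-only dropout, positive deg1 weights are local to drivers", {
  cfg <- synthetic_config(n_genes = 80L, n_instances = 6L, n_drivers = 4L,
                          driver_dropout = 0.8, background_flip = 0,
                          mutation_rate = 0, driver_removal = "driver", seed = 3L)
  H <- generate_network(cfg)
  gi <- generate_instances(cfg, H)
  iset <- build_instance_set(H, gi$instances)
  m <- differential_sum(iset, degree_order1)
  hot <- names(m$weights)[m$weights > 0]
  neighborhood <- unique(c(gi$gold,
                           unlist(lapply(igraph::adjacent_vertices(H, gi$gold),
                                         function(v) v$name))))
  expect_true(all(hot %in% neighborhood))
})

test_that("raising driver_dropout raises the drivers' differential weights", {
  lift <- function(dropout, seed) {
    cfg <- synthetic_config(n_genes = 100L, n_instances = 8L, n_drivers = 5L,
                            driver_dropout = dropout, background_flip = 0.02,
                            mutation_rate = 0.01, seed = seed)
    H <- generate_network(cfg)
    gi <- generate_instances(cfg, H)
    m <- differential_sum(build_instance_set(H, gi$instances), degree_order1)
    mean(m$weights[gi$gold]) - mean(m$weights[setdiff(names(m$weights), gi$gold)])
  }
  seeds <- 1:10
  low <- mean(vapply(seeds, function(s) lift(0.1, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) lift(0.4, s), numeric(1)))
  high <- mean(vapply(seeds, function(s) lift(0.8, s), numeric(1)))
  expect_lt(low, mid)
  expect_lt(mid, high)
})

test_that("the toy ontology has the planted level structure and annotation contrast", {
  cfg <- small_cfg()
  H <- generate_network(cfg)
  gi <- generate_instances(cfg, H)
  ann <- generate_go(cfg, gi$gold, setdiff(igraph::V(H)$name, gi$gold))
  ann_b <- generate_go(cfg, gi$gold, setdiff(igraph::V(H)$name, gi$gold))
  expect_identical(ann$annotations, ann_b$annotations)

  levels <- go_term_levels(ann$ontology)
  expect_gte(max(levels), 7L)
  expect_true(all(levels[grep("^TERM:GOLD", names(levels))] == 5L))
  expect_true(all(levels[grep("^TERM:DEEP", names(levels))] == 7L))

  # a depth-7 term resolves to a level-5 ancestor after restriction
  r5 <- restrict_go_level(ann, 5)
  deep_genes <- names(ann$annotations)[vapply(ann$annotations, function(t) {
    any(startsWith(t, "TERM:DEEP"))
  }, logical(1))]
  for (g in utils::head(deep_genes, 3)) {
    expect_true(any(startsWith(r5$annotations[[g]], "TERM:GOLD")))
  }

  # gold/gold similarity beats background/gold on average at level 5
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 1 else length(intersect(a, b)) / u
  }
  gold_pairs <- utils::combn(gi$gold, 2)
  gg <- mean(apply(gold_pairs, 2, function(p) {
    jac(r5$annotations[[p[1]]], r5$annotations[[p[2]]])
  }))
  bg <- setdiff(igraph::V(H)$name, gi$gold)[1:20]
  bgold <- mean(vapply(bg, function(b) {
    mean(vapply(gi$gold, function(g) jac(r5$annotations[[b]], r5$annotations[[g]]),
                numeric(1)))
  }, numeric(1)))
  expect_gt(gg, bgold)
})

test_that("written synthetic files round-trip through the package readers", {
  cfg <- synthetic_config(n_genes = 60L, n_instances = 5L, n_drivers = 4L, seed = 9L)
  dir <- withr::local_tempdir()
  out <- write_synthetic_data(cfg, dir)
  g <- read_edge_list(out$paths$network)
  expect_equal(igraph::vcount(g), 60L)
  expect_equal(igraph::ecount(g), igraph::ecount(out$network))

  calls <- call_expressed(read_expression(out$paths$expression), 1)
  for (inst in out$instances) {
    expect_setequal(calls[[inst$id]]$normal, inst$normal_expressed)
    expect_setequal(calls[[inst$id]]$tumor, inst$tumor_expressed)
  }
  muts <- call_mutated(read_mutations(out$paths$mutations))
  for (inst in out$instances) {
    if (length(inst$tumor_mutated) > 0) {
      expect_setequal(muts[[inst$id]], inst$tumor_mutated)
    }
  }
  expect_setequal(read_gene_list(out$paths$gold), out$gold)

  ont <- read_obo(out$paths$obo)
  ann <- read_gaf(out$paths$gaf, ont)
  expect_setequal(names(ann$annotations), names(out$annotation$annotations))
  expect_identical(ann$annotations[order(names(ann$annotations))],
                   lapply(out$annotation$annotations, sort)[
                     order(names(out$annotation$annotations))])
})
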