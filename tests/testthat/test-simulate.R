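test_that("configurations are validated against their invariants", {
  expect_error(sim_config(pathway_size_range = c(2, 10)), "filter")
  expect_error(sim_config(pathway_size_range = c(10, 3)), "min <= max")
  expect_error(sim_config(n_genes = 50, pathway_size_range = c(3, 60)),
               "infeasible")
  expect_error(sim_config(n_candidates = 20000), "universe")
  expect_error(sim_config(planted_module_size = 300), "n_nodes")
  expect_error(sim_config(signal_beta_a = 1.2), "0, 1")
  expect_error(sim_config(overlap_rate = 1.5), "0, 1")
  expect_error(sim_config(enrichment_odds = 0), "positive")
})

test_that("the generator is deterministic given a configuration", {
  cfg <- sim_config(seed = 42, n_genes = 400, n_pathways = 10, n_nodes = 60,
                    planted_module_size = 6)
  s1 <- suppressMessages(simulate_study(cfg))
  s2 <- suppressMessages(simulate_study(cfg))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the default configuration reproduces the emulated study's shape", {
  cfg <- sim_config(seed = 1)
  st <- suppressMessages(simulate_study(cfg))
  expect_equal(length(st$candidates), 133L)
  expect_equal(length(st$db), 69L)
  expect_true(all(pathway_sizes(st$db) >= 3 & pathway_sizes(st$db) <= 28))
  expect_equal(nrow(st$graph$nodes), 200L)
  expect_match(st$candidates, "^Sb\\d{2}g\\d{6}$")
  expect_equal(length(st$truth$planted_nodes), 15L)
})

test_that("empty generators return empty structures", {
  cfg0 <- sim_config(n_pathways = 0)
  expect_equal(length(generate_pathway_db(cfg0)), 0L)
  cfgc <- sim_config(n_candidates = 0)
  db <- generate_pathway_db(cfgc)
  expect_equal(generate_candidate_set(db, cfgc)$genes, character(0))
  cfgp <- sim_config(planted_module_size = 0, n_nodes = 50)
  g <- suppressMessages(generate_scored_graph(cfgp))
  expect_equal(g$truth$planted_nodes, character(0))
})

test_that("designated pairs overlap as requested; zero rate means chance level", {
  # overlap_rate = 0: expected shared genes of a designated pair is the
  # hypergeometric chance level K * n / N (averaged over seeds)
  shared0 <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, n_genes = 500, n_pathways = 2,
                      pathway_size_range = c(40, 40), overlap_rate = 0)
    db <- generate_pathway_db(cfg)
    length(intersect(db$sets[[1]], db$sets[[2]]))
  }, numeric(1))
  expected <- 40 * 40 / 500          # 3.2
  se <- sd(shared0) / sqrt(length(shared0))
  expect_lt(abs(mean(shared0) - expected), 3 * se + 1e-9)
  # positive rate: designated pairs share about rate * min size genes
  shared5 <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = 400 + s, n_genes = 500, n_pathways = 2,
                      pathway_size_range = c(40, 40), overlap_rate = 0.5)
    db <- generate_pathway_db(cfg)
    length(intersect(db$sets[[1]], db$sets[[2]]))
  }, numeric(1))
  expect_gt(mean(shared5), 18)   # core of 20 plus chance-level extras
})

test_that("planted modules are connected and carry the signal p-values", {
  cfg <- sim_config(seed = 9, n_nodes = 120, planted_module_size = 12,
                    signal_beta_a = 0.2)
  g <- suppressMessages(generate_scored_graph(cfg))
  keep <- g$edges$from %in% g$truth$planted_nodes &
    g$edges$to %in% g$truth$planted_nodes
  sub <- igraph::graph_from_data_frame(
    g$edges[keep, ], directed = FALSE,
    vertices = data.frame(name = g$truth$planted_nodes))
  expect_equal(igraph::components(sub)$no, 1L)
  full <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = data.frame(name = g$nodes$id))
  expect_equal(igraph::components(full)$no, 1L)  # repair makes it connected
  expect_true(all(g$nodes$p_value > 0 & g$nodes$p_value <= 1))
  # signal p-values are stochastically smaller than the background
  planted_p <- g$nodes$p_value[g$nodes$id %in% g$truth$planted_nodes]
  other_p <- g$nodes$p_value[!g$nodes$id %in% g$truth$planted_nodes]
  expect_lt(median(planted_p), median(other_p))
})

test_that("near-uniform signal shape is indistinguishable from background", {
  # as the beta shape approaches 1 the planted p-values lose their skew
  ks_p <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 800 + s, n_nodes = 300, planted_module_size = 100,
                      signal_beta_a = 0.99)
    g <- suppressMessages(generate_scored_graph(cfg))
    planted <- g$nodes$id %in% g$truth$planted_nodes
    suppressWarnings(stats::ks.test(g$nodes$p_value[planted],
                                    g$nodes$p_value[!planted])$p.value)
  }, numeric(1))
  expect_gt(median(ks_p), 0.01)
})
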