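test_that("similarity coefficients match hand enumeration", {
  expect_equal(jaccard(c("g1", "g2", "g3"), c("g1", "g2", "g3")), 1)
  expect_equal(jaccard(c("g1", "g2"), c("g3", "g4")), 0)
  expect_equal(jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  expect_equal(overlap_coefficient(c("g1", "g2"), c("g1", "g2", "g3")), 1)
  expect_equal(overlap_coefficient(c("g1", "g2"), c("g3", "g4")), 0)
  expect_equal(overlap_coefficient(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 2 / 3)
  expect_error(jaccard(character(0), character(0)), "empty")
  expect_error(overlap_coefficient(character(0), character(0)), "empty")
})

test_that("JC <= OC, symmetry, and brute-force agreement on random pairs", {
  set.seed(101)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:500) {
    a <- sample(pool, sample(1:30, 1))
    b <- sample(pool, sample(1:30, 1))
    jc <- jaccard(a, b); oc <- overlap_coefficient(a, b)
    expect_lte(jc, oc + 1e-15)
    expect_equal(jc, jaccard(b, a))
    expect_equal(oc, overlap_coefficient(b, a))
    ref <- brute_jc_oc(a, b)
    expect_equal(jc, unname(ref["jc"]))
    expect_equal(oc, unname(ref["oc"]))
  }
})

test_that("the gene-count filter keeps exactly the large-enough pathways", {
  db <- pathway_db(list(A = c("g1", "g2"), B = c("g1", "g2", "g3"),
                        C = c("g1", "g2", "g3", "g4")))
  flt <- filter_min_genes(db, 3)
  expect_setequal(names(flt), c("B", "C"))
  expect_identical(names(filter_min_genes(flt, 3)), names(flt))  # idempotent
  expect_equal(length(filter_min_genes(pathway_db(list()), 3)), 0L)
})

test_that("pair building applies the shared-gene filter and drops orphans", {
  db <- pathway_db(list(P1 = c("a", "b", "c", "d"), P2 = c("b", "c", "d", "e"),
                        P3 = c("x", "y", "z")))
  bp <- build_pairs(db, min_shared = 3)
  expect_setequal(names(bp$db), c("P1", "P2"))
  expect_equal(nrow(bp$pairs), 1L)
  expect_equal(bp$pairs$shared, 3L)
  expect_equal(bp$pairs$jc, 3 / 5)
  expect_equal(bp$pairs$oc, 3 / 4)
  # mutually disjoint collections give an empty valid set
  db2 <- pathway_db(list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3")))
  bp2 <- build_pairs(db2)
  expect_equal(length(bp2$db), 0L)
  expect_equal(nrow(bp2$pairs), 0L)
})

test_that("raising thresholds never adds pairs or edges (monotonicity)", {
  set.seed(33)
  for (rep in 1:10) {
    db <- random_pathway_db(n_pathways = 8, universe_size = 25)
    p1 <- build_pairs(db, min_shared = 1)$pairs
    p2 <- build_pairs(db, min_shared = 2)$pairs
    p3 <- build_pairs(db, min_shared = 3)$pairs
    key <- function(p) paste(p$pathway_a, p$pathway_b)
    expect_true(all(key(p2) %in% key(p1)))
    expect_true(all(key(p3) %in% key(p2)))
    cp <- crosstalk_pairs(db, min_shared = 1)
    loose <- suppressWarnings(rank_and_select(cp$pairs, fdr_max = 0.5, min_shared = 1))
    tight <- suppressWarnings(rank_and_select(cp$pairs, fdr_max = 0.05, min_shared = 1))
    expect_true(all(key(tight) %in% key(loose)))
    expect_true(all(tight$p_adj < 0.05))
  }
})

test_that("pair Fisher test delegates to the exact hypergeometric tail", {
  a <- sprintf("a%02d", 1:10); b <- c(a[1:5], sprintf("b%02d", 1:5))
  expect_equal(pair_fisher(a, b, 100), hypergeom_upper_tail(5, 10, 10, 100))
  # degenerate: identical sets spanning the whole universe
  u <- sprintf("u%02d", 1:10)
  expect_equal(pair_fisher(u, u, 10), 1)
  # disjoint sets: P(X >= 0) = 1 under the over-representation sidedness
  expect_equal(pair_fisher(c("x1", "x2"), c("y1", "y2"), 50), 1)
  expect_error(pair_fisher(a, b, 10), "universe")
})

test_that("edge selection ranks by similarity with deterministic tie-breaks", {
  pairs <- data.frame(
    pathway_a = c("A", "A", "B"), pathway_b = c("B", "C", "C"),
    shared = c(5L, 4L, 3L),
    jc = c(0.5, 0.3, 0.3), oc = c(0.7, 0.5, 0.5),
    p_adj = c(0.001, 0.005, 0.002),
    stringsAsFactors = FALSE
  )
  sel <- rank_and_select(pairs, fdr_max = 0.01)
  expect_equal(sel$rank_score, c(0.6, 0.4, 0.4))
  # equal rank scores: the smaller adjusted p comes first
  expect_equal(sel$pathway_a[2:3], c("B", "A"))
  # top_fraction keeps ceil(fraction * n)
  expect_equal(nrow(rank_and_select(pairs, fdr_max = 0.01, top_fraction = 0.5)), 2L)
  expect_error(rank_and_select(pairs, fdr_max = 0), "fdr_max")
  expect_warning(rank_and_select(pairs, fdr_max = 1e-6), "no pathway pair")
})

test_that("top-fraction selection reproduces the published pair arithmetic", {
  # 222 candidate pairs cut to the top 18% leaves ceil(0.18 * 222) = 40 edges
  set.seed(5)
  n <- 222
  nm <- sprintf("PW%03d", 1:60)
  pairs <- data.frame(
    pathway_a = sample(nm, n, replace = TRUE),
    pathway_b = sample(nm, n, replace = TRUE),
    shared = sample(3:10, n, replace = TRUE),
    jc = runif(n, 0.05, 0.6), stringsAsFactors = FALSE
  )
  pairs$oc <- pmin(1, pairs$jc + runif(n, 0, 0.3))
  pairs$p_adj <- runif(n, 0, 0.009)
  sel <- rank_and_select(pairs, fdr_max = 0.01, top_fraction = 0.18)
  expect_equal(nrow(sel), 40L)
})

test_that("network summaries match hand-computed values", {
  db <- pathway_db(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                        C = c("g1", "g3", "g4"), D = c("g1", "g2", "g4"),
                        E = c("g1", "g2", "g5")))
  tri <- data.frame(pathway_a = c("A", "A", "B"), pathway_b = c("B", "C", "C"),
                    shared = 3L, jc = 0.5, oc = 0.5, p_adj = 1e-4,
                    rank_score = 0.5)
  net <- build_network(tri, db)
  expect_equal(net$summary$avg_degree, 2)
  expect_equal(net$summary$avg_clustering, 1)
  star <- data.frame(pathway_a = "A", pathway_b = c("B", "C", "D"),
                     shared = 3L, jc = 0.5, oc = 0.5, p_adj = 1e-4,
                     rank_score = 0.5)
  net2 <- build_network(star, db)
  expect_equal(net2$summary$avg_degree, 1.5)
  expect_equal(net2$summary$avg_clustering, 0)
})

test_that("major modules are the functional classes with enough pathways", {
  # 8 amino-acid, 5 carbohydrate, 4 xenobiotics pathways plus 2 singletons:
  # exactly three major modules
  nm <- sprintf("PW%02d", 1:19)
  cls <- c(rep("Amino acid metabolism", 8), rep("Carbohydrate metabolism", 5),
           rep("Xenobiotics biodegradation and metabolism", 4),
           "Lipid metabolism", "Energy metabolism")
  sets <- stats::setNames(lapply(seq_along(nm), function(i) {
    sprintf("g%02d_%d", 1:4, i)
  }), nm)
  db <- pathway_db(sets, classes = cls)
  edges <- data.frame(pathway_a = nm[-length(nm)], pathway_b = nm[-1],
                      shared = 3L, jc = 0.4, oc = 0.6, p_adj = 1e-4,
                      rank_score = 0.5)
  net <- build_network(edges, db)
  expect_equal(net$summary$n_major_modules, 3L)
  expect_setequal(names(net$modules),
                  c("Amino acid metabolism", "Carbohydrate metabolism",
                    "Xenobiotics biodegradation and metabolism"))
  expect_equal(lengths(net$modules)[["Amino acid metabolism"]], 8L)
})
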