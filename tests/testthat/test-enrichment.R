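test_that("hypergeometric upper tail matches exact enumeration and phyper", {
  # frozen value computed by exact rational-arithmetic pmf summation
  # (sum_{i=5}^{10} C(10,i) C(90,10-i) / C(100,10))
  expect_equal(hypergeom_upper_tail(5, 10, 10, 100),
               6.7162774826505002e-04, tolerance = 1e-13)
  # degenerate cases
  expect_identical(hypergeom_upper_tail(0, 7, 5, 50), 1)
  expect_identical(hypergeom_upper_tail(3, 3, 10, 10), 1)
  # random margins against two independent routes: dhyper pmf summation and
  # phyper's survival function
  set.seed(42)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    got <- hypergeom_upper_tail(k, K, n, N)
    brute <- sum(dhyper(k:min(K, n), K, N - K, n))
    expect_equal(got, brute, tolerance = 1e-12)
    expect_equal(got, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail survives extreme magnitudes in log space", {
  # shape of a strong enrichment signal: k=75 of K=3705 in n=133 of N=40000
  p <- hypergeom_upper_tail(75, 3705, 133, 40000)
  expect_gt(p, 0)
  expect_lt(p, 1e-40)
  expect_equal(p, phyper(74, 3705, 40000 - 3705, 133, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("tail probability decreases as the overlap grows", {
  p <- hypergeom_upper_tail(0:10, 20, 10, 200)
  expect_true(all(diff(p) < 0))
})

test_that("inconsistent margins are rejected", {
  expect_error(hypergeom_upper_tail(5, 3, 10, 100), "margins")
  expect_error(hypergeom_upper_tail(2, 30, 10, 20), "margins")
  expect_error(hypergeom_upper_tail(-1, 3, 10, 100), "margins")
  expect_error(hypergeom_upper_tail(1, 3, 10, 2), "margins")
})

test_that("BH adjustment follows the step-up rule and matches p.adjust", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^2
    p <- pmax(p, 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
    m <- length(p) + sample(0:20, 1)
    expect_equal(bh_adjust(p, m_total = m), p.adjust(p, "BH", n = m),
                 tolerance = 1e-14)
  }
})

test_that("BH adjustment preserves order and never shrinks a p-value", {
  set.seed(11)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in the raw ranks
})

test_that("BH adjustment rejects out-of-range p-values", {
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1), m_total = 0), "m_total")
})

test_that("enrich reports exact counts and per-stratum adjustment", {
  db <- pathway_db(
    list(A = c("g1", "g2", "g3", "g4"),
         B = c("g3", "g4", "g5", "g6"),
         C = c("g7", "g8", "g9"),
         D = c("g10", "g11", "g12")),
    classes = c("P", "P", "F", "F")
  )
  res <- enrich(c("g1", "g2", "g3", "g9"), db, background_size = 50)
  expect_setequal(res$term_id, c("A", "B", "C"))
  expect_equal(res$k[res$term_id == "A"], 3L)
  expect_equal(res$n, rep(4L, 3))
  # raw p agrees with the exact tail for each row
  expect_equal(res$p_raw,
               hypergeom_upper_tail(res$k, res$K, res$n, res$N))
  # stratum "P" has two terms: the BH family size is 2 within it
  pa <- res[res$term_id == "A", ]
  pb <- res[res$term_id == "B", ]
  expect_equal(sort(c(pa$p_adj, pb$p_adj)),
               sort(bh_adjust(c(pa$p_raw, pb$p_raw), m_total = 2)))
  # stratum "F" has two terms but only one with overlap: m_total still 2
  pc <- res[res$term_id == "C", ]
  expect_equal(pc$p_adj, min(pc$p_raw * 2, 1))
  # sorted by raw p
  expect_true(!is.unsorted(res$p_raw))
})

test_that("a fully recovered pathway attains the minimum possible p", {
  sets <- split(sprintf("g%03d", 1:40), rep(1:8, each = 5))
  names(sets) <- sprintf("PW%d", 1:8)
  db <- pathway_db(sets)
  res <- enrich(sets$PW3, db, background_size = 200)
  expect_equal(res$term_id[1], "PW3")
  expect_equal(res$p_raw[1], hypergeom_upper_tail(5, 5, 5, 200))
})

test_that("empty queries warn and return no records", {
  db <- pathway_db(list(A = c("g1", "g2", "g3")))
  expect_warning(res <- enrich(character(0), db, background_size = 10), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("planted enrichment is detected at high power", {
  # strongly enriched planted pathways rank at the top in most replicates
  hits <- vapply(1:25, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_genes = 5000, n_pathways = 40,
                      pathway_size_range = c(40, 60), overlap_rate = 0,
                      n_candidates = 150, enrichment_odds = 10)
    db <- generate_pathway_db(cfg)
    cand <- generate_candidate_set(db, cfg)
    res <- enrich(cand$genes, db, background_size = cfg$n_genes)
    all(cand$truth$enriched_pathways %in% utils::head(res$term_id, 5))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
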