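# Shared fixture builders for the test suite. Everything is generated in code
# under fixed seeds; nothing is read from disk except the packaged summary
# tables under extdata.

# a tiny bum_fit with known parameters, bypassing estimation
fixed_bum <- function(lambda, a) {
  structure(list(lambda = lambda, a = a,
                 log_likelihood = NA_real_, n_points = NA_integer_,
                 pi0 = lambda + (1 - lambda) * a,
                 no_signal = FALSE),
            class = "bum_fit")
}

# scored graph straight from node scores (tau irrelevant for the search)
graph_from_scores <- function(scores, edges) {
  nodes <- data.frame(id = names(scores), p_value = 0.5, score = unname(scores),
                      stringsAsFactors = FALSE)
  smax <- max(nodes$score)
  edges <- data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE)
  edges$dist <- (smax - scores[edges$from]) + (smax - scores[edges$to])
  structure(list(nodes = nodes, edges = edges, tau = NA_real_, fit = NULL),
            class = "scored_graph")
}

# random connected graph over n nodes with uniform extra edges and random
# scores in [-2, 2]; always contains a spanning tree so it is connected
random_scored_graph <- function(n, extra = n, score_range = c(-2, 2)) {
  ids <- sprintf("v%02d", seq_len(n))
  from <- character(0); to <- character(0)
  if (n > 1) {
    anchor <- vapply(2:n, function(i) ids[sample.int(i - 1L, 1L)], character(1))
    from <- ids[-1L]; to <- anchor
  }
  if (extra > 0 && n > 2) {
    pairs <- t(utils::combn(ids, 2))
    pick <- sample(nrow(pairs), min(extra, nrow(pairs)))
    from <- c(from, pairs[pick, 1]); to <- c(to, pairs[pick, 2])
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b)) & a != b
  scores <- stats::setNames(stats::runif(n, score_range[1], score_range[2]), ids)
  graph_from_scores(scores, data.frame(from = a[keep], to = b[keep]))
}

# random free tree over n nodes via random attachment
random_tree <- function(n, score_range = c(-2, 2)) {
  ids <- sprintf("v%02d", seq_len(n))
  edges <- if (n > 1) {
    data.frame(from = ids[-1L],
               to = vapply(2:n, function(i) ids[sample.int(i - 1L, 1L)],
                           character(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  scores <- stats::setNames(stats::runif(n, score_range[1], score_range[2]), ids)
  list(edges = edges, scores = scores, nodes = ids)
}

# small random pathway collections for round-trip and property tests
random_pathway_db <- function(n_pathways = 6, universe_size = 40) {
  genes <- sprintf("Sb%02dg%06d", sample.int(10, universe_size, replace = TRUE),
                   sample.int(999999, universe_size))
  genes <- unique(genes)
  sets <- lapply(seq_len(n_pathways), function(i) {
    sample(genes, sample(3:min(12, length(genes)), 1))
  })
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  pathway_db(sets,
             classes = sample(c("Amino acid metabolism",
                                "Carbohydrate metabolism",
                                "Xenobiotics biodegradation and metabolism"),
                              n_pathways, replace = TRUE),
             ko = sprintf("ko%05d", sample.int(99999, n_pathways)))
}

# brute-force overlap coefficients by explicit element enumeration, written
# independently of the set-operation implementation
brute_jc_oc <- function(a, b) {
  a <- unique(a); b <- unique(b)
  all_elems <- unique(c(a, b))
  in_a <- all_elems %in% a
  in_b <- all_elems %in% b
  inter <- sum(in_a & in_b)
  union <- sum(in_a | in_b)
  c(jc = inter / union, oc = inter / min(sum(in_a), sum(in_b)))
}

f1_score <- function(found, truth) {
  tp <- length(intersect(found, truth))
  if (tp == 0) return(0)
  prec <- tp / length(found)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
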