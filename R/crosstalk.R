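#' Jaccard coefficient of two gene sets
#'
#' `|A intersect B| / |A union B|`. Together with the overlap coefficient this
#' is the pairwise similarity used to rank candidate pathway cross-talk edges.
#'
#' @param a,b Character vectors of gene IDs (duplicates ignored).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) stop("both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap coefficient of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; equals 1 whenever the smaller set is
#' contained in the larger, and is always at least the Jaccard coefficient.
#'
#' @inheritParams jaccard
#' @return A number in \[0, 1\].
#' @examples
#' overlap_coefficient(c("g1", "g2", "g3"), c("g2", "g3", "g4"))  # 2/3
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) stop("both sets are empty")
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Drop pathways with too few member genes
#'
#' Removes pathways containing fewer than `min_genes` genes; pathways with very
#' few candidate genes carry too little information for cross-talk analysis.
#' Idempotent.
#'
#' @param db A [pathway_db()].
#' @param min_genes Minimum member count to keep (default 3).
#' @return The filtered `pathway_db`.
#' @export
filter_min_genes <- function(db, min_genes = 3) {
  stopifnot(inherits(db, "pathway_db"), min_genes >= 1)
  db[lengths(db$sets) >= min_genes]
}

#' Enumerate candidate cross-talk pairs
#'
#' Forms every unordered pathway pair sharing at least `min_shared` genes and
#' computes the Jaccard and overlap coefficients for each. Pathways that share
#' enough genes with no other pathway are dropped from the "valid" collection,
#' since they cannot participate in any cross-talk edge.
#'
#' @param db A [pathway_db()], already size-filtered (see [filter_min_genes()]).
#' @param min_shared Minimum shared-gene count for a pair (default 3).
#' @return A list with `db` (the valid pathways) and `pairs`, a data frame with
#'   columns `pathway_a`, `pathway_b` (lexicographically ordered within each
#'   row), `shared`, `jc`, `oc`.
#' @export
build_pairs <- function(db, min_shared = 3) {
  stopifnot(inherits(db, "pathway_db"), min_shared >= 1)
  empty <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      shared = integer(0), jc = numeric(0), oc = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(db) < 2) return(list(db = db[0], pairs = empty))
  nm <- sort(names(db))
  cmb <- utils::combn(nm, 2)
  shared <- integer(ncol(cmb)); jc <- numeric(ncol(cmb)); oc <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- db$sets[[cmb[1, i]]]; b <- db$sets[[cmb[2, i]]]
    s <- length(intersect(a, b))
    shared[i] <- s
    jc[i] <- s / length(union(a, b))
    oc[i] <- s / min(length(a), length(b))
  }
  keep <- shared >= min_shared
  pairs <- data.frame(pathway_a = cmb[1, keep], pathway_b = cmb[2, keep],
                      shared = shared[keep], jc = jc[keep], oc = oc[keep],
                      stringsAsFactors = FALSE)
  valid <- sort(unique(c(pairs$pathway_a, pairs$pathway_b)))
  list(db = db[valid], pairs = pairs)
}

#' Fisher's exact p-value for one pathway pair's gene overlap
#'
#' One-sided over-representation p-value from the 2x2 table
#' (`|A^B|`, `|A\\B|`, `|B\\A|`, rest of the universe), computed via the exact
#' hypergeometric upper tail.
#'
#' @param a,b Character vectors: the two pathways' member genes.
#' @param universe_size Size of the gene universe the pair is tested against
#'   (by default in this package: the candidate genes covered by at least one
#'   valid pathway).
#' @return A p-value.
#' @export
pair_fisher <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (universe_size < length(union(a, b))) {
    stop("universe smaller than |A union B|")
  }
  hypergeom_upper_tail(length(intersect(a, b)), length(a), length(b),
                       universe_size)
}

#' Score all cross-talk pairs with overlap significance
#'
#' Runs [build_pairs()] then attaches per-pair Fisher p-values and BH-adjusted
#' q-values (family = all tested pairs).
#'
#' @inheritParams build_pairs
#' @param universe_size Universe for the pair tests; defaults to the number of
#'   genes covered by at least one valid pathway.
#' @return A list with `db` (valid pathways) and `pairs` (with `p_raw`,
#'   `p_adj` columns added).
#' @export
crosstalk_pairs <- function(db, min_shared = 3, universe_size = NULL) {
  bp <- build_pairs(db, min_shared = min_shared)
  pairs <- bp$pairs
  if (nrow(pairs) == 0) {
    pairs$p_raw <- numeric(0)
    pairs$p_adj <- numeric(0)
    return(list(db = bp$db, pairs = pairs))
  }
  if (is.null(universe_size)) universe_size <- length(pathway_universe(bp$db))
  pairs$p_raw <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_fisher(bp$db$sets[[pairs$pathway_a[i]]],
                bp$db$sets[[pairs$pathway_b[i]]], universe_size)
  }, numeric(1))
  pairs$p_adj <- bh_adjust(pairs$p_raw)
  list(db = bp$db, pairs = pairs)
}

#' Rank cross-talk pairs and select the final edge set
#'
#' Keeps pairs passing the FDR and shared-gene thresholds, scores each by the
#' requested combination of Jaccard and overlap coefficients, and sorts by
#' score (descending), breaking ties by ascending adjusted p-value and then by
#' pair name. Optionally retains only the top fraction of the sorted list
#' (`ceiling(top_fraction * n)` edges, so the stated fraction is never
#' undershot).
#'
#' @param pairs Data frame from [crosstalk_pairs()] (must carry `p_adj`).
#' @param fdr_max Maximum adjusted p-value for an edge (default 0.01).
#' @param min_shared Minimum shared-gene count (default 3).
#' @param top_fraction Optional fraction in (0, 1\] of the ranked, filtered
#'   edges to retain.
#' @param rank_by `"mean"` (arithmetic mean of JC and OC, the default),
#'   `"jc"`, or `"oc"`.
#' @return The selected edges with a `rank_score` column, ordered by rank.
#' @export
rank_and_select <- function(pairs, fdr_max = 0.01, min_shared = 3,
                            top_fraction = NULL, rank_by = c("mean", "jc", "oc")) {
  rank_by <- match.arg(rank_by)
  if (!is.numeric(fdr_max) || length(fdr_max) != 1 || fdr_max <= 0 || fdr_max > 1) {
    stop("`fdr_max` must lie in (0, 1]")
  }
  if (is.null(pairs$p_adj)) stop("`pairs` must carry BH-adjusted p-values (`p_adj`)")
  sel <- pairs[pairs$p_adj < fdr_max & pairs$shared >= min_shared, , drop = FALSE]
  sel$rank_score <- switch(rank_by,
    mean = (sel$jc + sel$oc) / 2,
    jc = sel$jc,
    oc = sel$oc
  )
  sel <- sel[order(-sel$rank_score, sel$p_adj, sel$pathway_a, sel$pathway_b), ,
             drop = FALSE]
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) stop("`top_fraction` must lie in (0, 1]")
    sel <- utils::head(sel, ceiling(top_fraction * nrow(sel)))
  }
  if (nrow(sel) == 0) warning("no pathway pair passes the selection thresholds")
  rownames(sel) <- NULL
  sel
}

#' Assemble the pathway cross-talk network
#'
#' Builds an undirected network whose nodes are pathways (attributed with
#' functional class and gene count) and whose edges are the selected
#' cross-talk pairs. Functional classes represented by at least four pathways
#' in the network are reported as major modules. Summary statistics are the
#' node and edge counts, the average node degree (`2E/V`) and the average
#' local clustering coefficient (nodes of degree < 2 contribute 0).
#'
#' @param edges Data frame of selected edges (from [rank_and_select()]).
#' @param db The [pathway_db()] the edges refer to.
#' @param min_module_size Node count for a functional class to form a major
#'   module (default 4).
#' @return A `crosstalk_network`: list with `graph` (igraph), `nodes`, `edges`,
#'   `modules` (named list of node sets) and `summary`.
#' @export
build_network <- function(edges, db, min_module_size = 4) {
  stopifnot(inherits(db, "pathway_db"))
  if (nrow(edges) == 0) warning("building a network from an empty edge set")
  node_ids <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  nodes <- data.frame(
    pathway = node_ids,
    functional_class = db$classes[node_ids],
    n_genes = as.integer(lengths(db$sets[node_ids])),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges[, setdiff(names(edges), character(0)), drop = FALSE],
    directed = FALSE, vertices = nodes
  )
  deg <- igraph::degree(g)
  cc <- if (length(node_ids) > 0) {
    igraph::transitivity(g, type = "local", isolates = "zero")
  } else numeric(0)
  nodes$degree <- as.integer(deg[nodes$pathway])
  cls <- split(nodes$pathway, nodes$functional_class)
  modules <- cls[vapply(cls, length, integer(1)) >= min_module_size]
  summary <- list(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    avg_degree = if (nrow(nodes) > 0) 2 * nrow(edges) / nrow(nodes) else NA_real_,
    avg_clustering = if (nrow(nodes) > 0) mean(cc) else NA_real_,
    n_major_modules = length(modules)
  )
  structure(list(graph = g, nodes = nodes, edges = edges,
                 modules = modules, summary = summary),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<crosstalk_network> %d pathways, %d edges\n", s$n_nodes, s$n_edges))
  cat(sprintf("  average degree %.3f, average clustering %.3f\n",
              s$avg_degree, s$avg_clustering))
  if (length(x$modules) > 0) {
    cat(sprintf("  %d major module(s): %s\n", length(x$modules),
                paste(sprintf("%s (%d)", names(x$modules),
                              lengths(x$modules)), collapse = "; ")))
  } else {
    cat("  no major modules\n")
  }
  invisible(x)
}
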