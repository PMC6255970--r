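#' @rdname extract_subnetwork
#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d node(s), total score %.4f (method: %s)\n",
              length(x$nodes), x$total_score, x$method))
  invisible(x)
}

.subnetwork <- function(nodes, total_score, method) {
  structure(list(nodes = sort(nodes), total_score = total_score,
                 connected = TRUE, method = method),
            class = "subnetwork")
}

# Preference order for equal-scoring candidate subnetworks: higher score, then
# fewer nodes, then lexicographically smaller node set.
.better_subnet <- function(a, b, tol = 1e-9) {
  if (is.null(b)) return(TRUE)
  if (a$total_score > b$total_score + tol) return(TRUE)
  if (a$total_score < b$total_score - tol) return(FALSE)
  if (length(a$nodes) != length(b$nodes)) return(length(a$nodes) < length(b$nodes))
  paste(a$nodes, collapse = "\r") < paste(b$nodes, collapse = "\r")
}

#' Maximum-weight connected subtree by dynamic programming
#'
#' Exactly solves the maximum-score connected subgraph problem restricted to a
#' tree (or forest): rooted at the smallest node ID, each vertex's best
#' achievable subtree score is `best(v) = s(v) + sum over children of
#' max(0, best(child))`; the answer is traced back from the best vertex. On a
#' forest, each component is solved and the best result returned.
#'
#' @param tree A data frame of tree edges (`from`, `to`), e.g. from
#'   [spanning_tree()]; must be acyclic. Isolated nodes can be supplied via a
#'   `nodes` attribute or the `nodes` argument.
#' @param scores Named numeric vector of node scores covering every tree node.
#' @param nodes Optional character vector of all node IDs (defaults to the
#'   tree's `nodes` attribute, or the edge endpoints).
#' @return A `subnetwork` with `method = "tree-dp"`.
#' @examples
#' tree <- data.frame(from = c("a", "b"), to = c("b", "c"))
#' max_weight_subtree(tree, c(a = 2, b = -1, c = 2))  # all three nodes, score 3
#' @export
max_weight_subtree <- function(tree, scores, nodes = NULL) {
  if (is.null(nodes)) nodes <- attr(tree, "nodes")
  if (is.null(nodes)) nodes <- unique(c(tree$from, tree$to))
  nodes <- sort(as.character(nodes))
  if (length(nodes) == 0) stop("empty tree")
  missing_s <- setdiff(nodes, names(scores))
  if (length(missing_s) > 0) {
    stop("missing score for node(s): ", paste(utils::head(missing_s, 5), collapse = ", "))
  }
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  ne <- if (is.null(tree)) 0L else nrow(tree)
  # cycle check doubles as the component labelling
  parent_uf <- seq_len(n)
  find <- function(i) {
    while (parent_uf[i] != i) {
      parent_uf[i] <<- parent_uf[parent_uf[i]]
      i <- parent_uf[i]
    }
    i
  }
  adj <- vector("list", n)
  for (e in seq_len(ne)) {
    u <- idx[[tree$from[e]]]; v <- idx[[tree$to[e]]]
    ra <- find(u); rb <- find(v)
    if (ra == rb) stop("input contains a cycle; not a tree")
    parent_uf[ra] <- rb
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  s <- as.numeric(scores[nodes])
  best_overall <- NULL
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    root <- members[1L]           # nodes are sorted, so this is the smallest ID
    # iterative BFS ordering, children processed before parents in reverse
    order_bfs <- integer(0)
    parent <- rep(0L, n)
    queue <- root; parent[root] <- -1L
    while (length(queue) > 0) {
      u <- queue[1L]; queue <- queue[-1L]
      order_bfs <- c(order_bfs, u)
      for (v in adj[[u]]) {
        if (parent[v] == 0L) {
          parent[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    best <- s
    for (u in rev(order_bfs)) {
      if (parent[u] > 0L && best[u] > 0) {
        best[parent[u]] <- best[parent[u]] + best[u]
      }
    }
    top <- members[which.max(best[members])]   # first max = smallest ID
    take <- logical(n)
    stack <- top
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      take[u] <- TRUE
      for (v in adj[[u]]) {
        if (parent[v] == u && best[v] > 0) stack <- c(stack, v)
      }
    }
    cand <- .subnetwork(nodes[take], sum(s[take]), "tree-dp")
    if (.better_subnet(cand, best_overall)) best_overall <- cand
  }
  best_overall
}

# add every positive-score neighbour reachable from the member set
# (order-independent closure)
.positive_closure <- function(members, edges, scores) {
  repeat {
    touch <- c(edges$to[edges$from %in% members],
               edges$from[edges$to %in% members])
    add <- setdiff(touch[scores[touch] > 0], members)
    if (length(add) == 0) return(members)
    members <- c(members, unique(add))
  }
}

# drop negative-score members that are not articulation points of the induced
# subgraph (removing them improves the score and keeps the module connected);
# worst offender first, to a fixpoint
.prune_negative <- function(members, edges, scores) {
  while (length(members) > 1) {
    keep <- edges$from %in% members & edges$to %in% members
    sub <- igraph::graph_from_data_frame(edges[keep, c("from", "to")],
                                         directed = FALSE,
                                         vertices = data.frame(name = members))
    arts <- igraph::as_ids(igraph::articulation_points(sub))
    cand <- members[scores[members] < 0 & !(members %in% arts)]
    if (length(cand) == 0) break
    members <- setdiff(members, cand[which.min(scores[cand])])
  }
  members
}

# lookahead across negative bridges: tentatively admit a nonpositive
# neighbour v, take the positive closure it unlocks, prune redundant negative
# nodes, and keep the move only if the total improves. This captures paths
# running from the module through negative nodes to positive nodes the
# spanning tree missed, and lets a cheaper bridge displace a costlier one.
.bridge_expand <- function(members, edges, scores) {
  members <- .prune_negative(members, edges, scores)
  repeat {
    improved <- FALSE
    touch <- unique(c(edges$to[edges$from %in% members],
                      edges$from[edges$to %in% members]))
    for (v in sort(setdiff(touch[scores[touch] <= 0], members))) {
      trial <- .positive_closure(c(members, v), edges, scores)
      trial <- .prune_negative(trial, edges, scores)
      if (sum(scores[trial]) > sum(scores[members]) + 1e-12) {
        members <- trial
        improved <- TRUE
      }
    }
    if (!improved) return(members)
  }
}

#' Extract the maximal-scoring subnetwork of a scored graph
#'
#' Heuristic pipeline for the maximum-score connected subgraph (Heinz-style
#' active module) problem: project the graph onto a minimum spanning tree over
#' the score-derived edge distances, solve the tree exactly by dynamic
#' programming ([max_weight_subtree()]), greedily augment with any neighboring
#' positive-score node in the original graph, and finally admit negative
#' bridge nodes whose inclusion unlocks enough positive neighbors to raise the
#' total score (the paths between positive and negative nodes). Both spanning
#' tree algorithms are tried and the better result kept. Disconnected graphs
#' are handled per component and the best-scoring result returned.
#'
#' @param graph A `scored_graph` from [score_nodes()].
#' @param algorithm Spanning tree algorithm(s) to try: `"prim"`, `"kruskal"`,
#'   or both (the default).
#' @return A `subnetwork` with `method = "augmented"`.
#' @export
extract_subnetwork <- function(graph, algorithm = c("prim", "kruskal")) {
  algorithm <- match.arg(algorithm, several.ok = TRUE)
  gp <- .graph_parts(graph)
  scores <- stats::setNames(graph$nodes$score, graph$nodes$id)
  best <- NULL
  for (alg in algorithm) {
    tree <- spanning_tree(graph, algorithm = alg)
    dp <- max_weight_subtree(tree, scores, nodes = gp$nodes)
    members <- .positive_closure(dp$nodes, gp$edges, scores)
    members <- .bridge_expand(members, gp$edges, scores)
    cand <- .subnetwork(members, sum(scores[members]), "augmented")
    if (.better_subnet(cand, best)) best <- cand
  }
  best
}

#' Exhaustive maximum-score connected subgraph (small-instance oracle)
#'
#' Enumerates every connected induced subgraph of a small graph and returns
#' the one with maximal total node score (ties: fewer nodes, then
#' lexicographically smallest node set). Provably optimal; intended as a
#' verification oracle for [extract_subnetwork()] on instances of at most
#' `max_nodes` nodes.
#'
#' @param graph A `scored_graph` (or compatible list with scored nodes).
#' @param max_nodes Refusal threshold (default 15); enumeration is `O(2^V)`.
#' @return A `subnetwork` with `method = "exhaustive"`.
#' @export
exhaustive_oracle <- function(graph, max_nodes = 15) {
  gp <- .graph_parts(graph)
  nodes <- sort(gp$nodes)
  n <- length(nodes)
  if (n > max_nodes) {
    stop(sprintf("graph has %d nodes; exhaustive enumeration is limited to %d",
                 n, max_nodes))
  }
  if (n == 0) stop("empty graph")
  s <- stats::setNames(graph$nodes$score, graph$nodes$id)[nodes]
  idx <- stats::setNames(seq_len(n), nodes)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  adj_mask <- integer(n)
  for (e in seq_len(nrow(gp$edges))) {
    u <- idx[[gp$edges$from[e]]]; v <- idx[[gp$edges$to[e]]]
    if (u == v) next
    adj_mask[u] <- bitwOr(adj_mask[u], bit[v])
    adj_mask[v] <- bitwOr(adj_mask[v], bit[u])
  }
  best <- NULL
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    members <- which(bitwAnd(mask, bit) != 0L)
    reached <- bit[members[1L]]
    repeat {
      frontier <- 0L
      for (u in members) {
        if (bitwAnd(reached, bit[u]) != 0L) {
          frontier <- bitwOr(frontier, adj_mask[u])
        }
      }
      grown <- bitwOr(reached, bitwAnd(frontier, mask))
      if (grown == reached) break
      reached <- grown
    }
    if (reached != mask) next
    cand <- .subnetwork(nodes[members], sum(s[members]), "exhaustive")
    if (.better_subnet(cand, best)) best <- cand
  }
  best
}
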