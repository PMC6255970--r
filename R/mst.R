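# Minimum spanning trees over scored-edge distances.
#
# Prim's and Kruskal's algorithms are implemented independently so each can
# serve as a cross-check on the other (their total weights must agree exactly;
# their edge sets must agree whenever all distances are distinct). Both handle
# disconnected inputs by returning a spanning forest, one tree per component.

.edge_weights <- function(edges) {
  w <- edges$dist
  if (is.null(w)) w <- edges$weight
  if (is.null(w)) stop("edges must carry a `dist` or `weight` column")
  as.numeric(w)
}

.graph_parts <- function(graph) {
  if (inherits(graph, "scored_graph") ||
      (is.list(graph) && !is.null(graph$nodes) && !is.null(graph$edges))) {
    list(nodes = as.character(graph$nodes$id), edges = graph$edges)
  } else {
    stop("`graph` must be a scored_graph or a list with `nodes` and `edges`")
  }
}

.components_of <- function(nodes, from, to) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ra <- find(idx[[from[e]]]); rb <- find(idx[[to[e]]])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_along(nodes), find, integer(1))
}

# Prim: dense O(V^2) key-array variant, adequate for the network sizes this
# package targets (hundreds to a few thousand nodes). Deterministic: the
# start vertex is the component's smallest ID and key ties resolve to the
# smallest-ID vertex.
.mst_prim_component <- function(nodes, edges, w) {
  nodes <- sort(nodes)
  n <- length(nodes)
  if (n <= 1) return(integer(0))
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    u <- idx[[edges$from[e]]]; v <- idx[[edges$to[e]]]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  in_tree <- logical(n)
  key <- rep(Inf, n)
  via_edge <- integer(n)
  key[1] <- 0
  chosen <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(!in_tree & is.finite(key))
    if (length(cand) == 0) break
    u <- cand[which.min(key[cand])]   # which.min takes the first = smallest ID
    in_tree[u] <- TRUE
    if (via_edge[u] > 0) chosen <- c(chosen, via_edge[u])
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; e <- nb[r, 2]
        if (!in_tree[v] && w[e] < key[v]) {
          key[v] <- w[e]
          via_edge[v] <- e
        }
      }
    }
  }
  chosen
}

.mst_kruskal <- function(nodes, edges, w) {
  ord <- order(w, edges$from, edges$to)
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chosen <- integer(0)
  for (e in ord) {
    ra <- find(idx[[edges$from[e]]]); rb <- find(idx[[edges$to[e]]])
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, e)
    }
  }
  chosen
}

#' Minimum spanning tree (or forest) of a scored graph
#'
#' Computes the minimum spanning tree over edge distances with either Prim's
#' or Kruskal's algorithm (two independent implementations; their total
#' weights always agree). Disconnected graphs yield one tree per connected
#' component.
#'
#' @param graph A `scored_graph` (see [score_nodes()]) or a list with `nodes`
#'   (data frame with `id`) and `edges` (data frame with `from`, `to` and a
#'   `dist` or `weight` column).
#' @param algorithm `"prim"` or `"kruskal"`.
#' @return A data frame of tree edges (same columns as the input edges), with
#'   attributes `nodes` (all node IDs) and `total_weight`.
#' @export
spanning_tree <- function(graph, algorithm = c("prim", "kruskal")) {
  algorithm <- match.arg(algorithm)
  gp <- .graph_parts(graph)
  nodes <- gp$nodes; edges <- gp$edges
  if (length(nodes) == 0) stop("empty graph")
  w <- .edge_weights(edges)
  if (algorithm == "kruskal") {
    chosen <- .mst_kruskal(nodes, edges, w)
  } else {
    comp <- .components_of(nodes, edges$from, edges$to)
    chosen <- integer(0)
    for (cid in unique(comp)) {
      cn <- nodes[comp == cid]
      ce <- which(edges$from %in% cn)   # both endpoints share the component
      chosen <- c(chosen, ce[.mst_prim_component(cn, edges[ce, , drop = FALSE],
                                                 w[ce])])
    }
  }
  tree <- edges[sort(chosen), , drop = FALSE]
  rownames(tree) <- NULL
  attr(tree, "nodes") <- nodes
  attr(tree, "total_weight") <- sum(w[chosen])
  tree
}
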