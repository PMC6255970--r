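# Synthetic study generator.
#
# Emulates the shape of a candidate-gene drought study in sorghum: a gene
# universe of ~1e4 loci with Sb{chrom}g{6-digit} IDs, a KEGG-style pathway
# collection (~69 pathways of 3-28 genes with functional-class labels), a
# prioritized candidate panel (~133 genes) enriched in chosen pathways at a
# controlled odds ratio, and a PPI graph whose planted connected module
# carries Beta(a, 1) signal p-values against a Uniform(0, 1) background.

.functional_class_vocab <- c(
  "Amino acid metabolism",
  "Biosynthesis of other secondary metabolites",
  "Carbohydrate metabolism",
  "Carbon metabolism",
  "Energy metabolism",
  "Environmental Information Processing; Signal transduction",
  "Glycan biosynthesis and metabolism",
  "Lipid metabolism",
  "Metabolism of cofactors and vitamins",
  "Metabolism of other amino acids",
  "Metabolism of terpenoids and polyketides",
  "Nucleotide metabolism",
  "Xenobiotics biodegradation and metabolism"
)

.gene_universe <- function(n) {
  sprintf("Sb%02dg%06d", (seq_len(n) - 1L) %% 10L + 1L, seq_len(n))
}

#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the generator with validation. Defaults reproduce
#' the shape of the emulated study: a universe of 10,000 genes, 69 pathways of
#' 3 to 28 genes, a 133-gene candidate panel enriched (odds ratio 25, strong
#' enough that the designated pathways are confidently detectable) in three
#' designated pathways, and a 200-node interaction graph with a planted
#' 15-node module whose p-values follow Beta(0.2, 1).
#'
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param n_genes Universe size.
#' @param n_pathways Number of pathways to generate.
#' @param pathway_size_range Length-2 integer vector (min, max); the minimum
#'   must be at least 3 so generated pathways can survive the gene-count
#'   filter.
#' @param overlap_rate Expected shared-gene fraction (of the smaller set) for
#'   designated pathway pairs, in \[0, 1\]. Pairs (1,2), (3,4), ... are the
#'   designated overlapping pairs.
#' @param n_candidates Candidate panel size.
#' @param enriched_pathway_ids Names of pathways the panel is enriched in;
#'   `NULL` means the first three generated pathways.
#' @param enrichment_odds Odds ratio (> 0) of candidate membership for genes
#'   inside vs outside the enriched pathways; 1 means no enrichment.
#' @param n_nodes Interaction graph size.
#' @param edge_model `"random-uniform"` (Erdos-Renyi G(n, m)) or
#'   `"preferential-attachment"` (Barabasi-Albert).
#' @param mean_degree Target average degree of the background graph.
#' @param planted_module_size Size of the planted connected signal module
#'   (0 disables planting).
#' @param signal_beta_a Shape `a` in (0, 1) of the Beta(a, 1) signal p-values.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10000L,
                       n_pathways = 69L,
                       pathway_size_range = c(3L, 28L),
                       overlap_rate = 0.3,
                       n_candidates = 133L,
                       enriched_pathway_ids = NULL,
                       enrichment_odds = 25,
                       n_nodes = 200L,
                       edge_model = c("random-uniform", "preferential-attachment"),
                       mean_degree = 4,
                       planted_module_size = 15L,
                       signal_beta_a = 0.2) {
  edge_model <- match.arg(edge_model)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 10) stop("`seed` must be a 32-bit integer")
  if (length(pathway_size_range) != 2 ||
      pathway_size_range[1] > pathway_size_range[2]) {
    stop("`pathway_size_range` must be (min, max) with min <= max")
  }
  if (pathway_size_range[1] < 3) {
    stop("`pathway_size_range` minimum must be >= 3 so pathways can pass the gene-count filter")
  }
  if (n_pathways > 0 && pathway_size_range[2] > n_genes) {
    stop("pathway size range infeasible for a universe of ", n_genes, " genes")
  }
  if (overlap_rate < 0 || overlap_rate > 1) stop("`overlap_rate` must lie in [0, 1]")
  if (n_candidates > n_genes) stop("`n_candidates` exceeds the gene universe")
  if (enrichment_odds <= 0) stop("`enrichment_odds` must be positive")
  if (planted_module_size > n_nodes) stop("`planted_module_size` exceeds `n_nodes`")
  if (signal_beta_a <= 0 || signal_beta_a >= 1) stop("`signal_beta_a` must lie in (0, 1)")
  if (mean_degree <= 0) stop("`mean_degree` must be positive")
  structure(list(
    seed = seed, n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_rate = overlap_rate,
    n_candidates = as.integer(n_candidates),
    enriched_pathway_ids = enriched_pathway_ids,
    enrichment_odds = enrichment_odds,
    n_nodes = as.integer(n_nodes), edge_model = edge_model,
    mean_degree = mean_degree,
    planted_module_size = as.integer(planted_module_size),
    signal_beta_a = signal_beta_a
  ), class = "sim_config")
}

#' Generate a pathway collection with controlled pairwise overlap
#'
#' Draws `n_pathways` gene sets from the universe. Designated pairs
#' ((1,2), (3,4), ...) share a core gene pool of expected size
#' `overlap_rate * min(sizes)`, giving direct control of their intersection;
#' all other membership is uniform, so undesignated pairs overlap at
#' hypergeometric chance level. Every pathway carries a functional-class
#' label from a fixed KEGG-style vocabulary and a synthetic `ko` identifier.
#'
#' @param cfg A [sim_config()].
#' @return A [pathway_db()].
#' @export
generate_pathway_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pathways == 0) return(pathway_db(list()))
  withr::with_seed(cfg$seed, {
    universe <- .gene_universe(cfg$n_genes)
    size_choices <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                     replace = TRUE)]
    nm <- sprintf("PW%03d", seq_len(cfg$n_pathways))
    classes <- sample(.functional_class_vocab, cfg$n_pathways, replace = TRUE)
    ko <- sprintf("ko%05d", sample.int(99999L, cfg$n_pathways))
    sets <- vector("list", cfg$n_pathways)
    names(sets) <- nm
    designated <- if (cfg$overlap_rate > 0 && cfg$n_pathways >= 2) {
      seq(1L, cfg$n_pathways - 1L, by = 2L)
    } else integer(0)
    done <- logical(cfg$n_pathways)
    for (i in designated) {
      j <- i + 1L
      n_core <- round(cfg$overlap_rate * min(sizes[i], sizes[j]))
      core <- sample(universe, n_core)
      rest <- setdiff(universe, core)
      sets[[i]] <- c(core, sample(rest, sizes[i] - n_core))
      sets[[j]] <- c(core, sample(rest, sizes[j] - n_core))
      done[c(i, j)] <- TRUE
    }
    for (i in which(!done)) sets[[i]] <- sample(universe, sizes[i])
    pathway_db(sets, classes = classes, ko = ko)
  })
}

#' Generate a candidate gene panel enriched in designated pathways
#'
#' Samples `n_candidates` genes without replacement from the universe, with
#' sampling weight `enrichment_odds` for genes belonging to any enriched
#' pathway and 1 otherwise. With odds 1 the draw is uniform, so downstream
#' enrichment p-values are calibrated under the null.
#'
#' @param db The [pathway_db()] the panel is enriched against.
#' @param cfg A [sim_config()]; `enriched_pathway_ids` must name pathways in
#'   `db` (or be `NULL` for the first three).
#' @return A list with `genes` (character vector) and `truth`
#'   (`enriched_pathways`).
#' @export
generate_candidate_set <- function(db, cfg) {
  stopifnot(inherits(db, "pathway_db"), inherits(cfg, "sim_config"))
  if (cfg$n_candidates > cfg$n_genes) stop("`n_candidates` exceeds the gene universe")
  enriched <- cfg$enriched_pathway_ids
  if (is.null(enriched)) enriched <- utils::head(names(db), 3L)
  if (!all(enriched %in% names(db))) {
    stop("unknown enriched pathway(s): ",
         paste(setdiff(enriched, names(db)), collapse = ", "))
  }
  withr::with_seed(cfg$seed + 1L, {
    universe <- .gene_universe(cfg$n_genes)
    if (cfg$n_candidates == 0) {
      genes <- character(0)
    } else {
      w <- rep(1, cfg$n_genes)
      inside <- universe %in% unlist(db$sets[enriched], use.names = FALSE)
      w[inside] <- cfg$enrichment_odds
      genes <- sample(universe, cfg$n_candidates, prob = w)
    }
    list(genes = sort(genes),
         truth = list(enriched_pathways = enriched))
  })
}

#' Generate an interaction graph with a planted signal module
#'
#' Builds a simple undirected background graph (Erdos-Renyi or preferential
#' attachment), plants a connected module of `planted_module_size` nodes
#' (joined by a random spanning tree), assigns planted nodes p-values drawn
#' from Beta(a, 1) and all others from Uniform(0, 1), and finally reconnects
#' any isolated components to the largest one by the minimum number of
#' bridging edges, chosen deterministically by sorted node ID (each repair is
#' reported via `message()`).
#'
#' @param cfg A [sim_config()].
#' @return A list with `nodes` (data frame `id`, `p_value`), `edges`
#'   (data frame `from`, `to`), and `truth` (`planted_nodes`).
#' @export
generate_scored_graph <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$planted_module_size > cfg$n_nodes) {
    stop("`planted_module_size` exceeds `n_nodes`")
  }
  withr::with_seed(cfg$seed + 2L, {
    ids <- .gene_universe(cfg$n_nodes)
    n <- cfg$n_nodes
    m_bg <- max(0L, round(cfg$mean_degree * n / 2))
    g <- if (cfg$edge_model == "random-uniform") {
      igraph::sample_gnm(n, min(m_bg, n * (n - 1) / 2))
    } else {
      igraph::sample_pa(n, m = max(1L, round(cfg$mean_degree / 2)),
                        directed = FALSE)
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                        stringsAsFactors = FALSE)
    planted <- sort(sample(ids, cfg$planted_module_size))
    if (length(planted) >= 2) {
      anchor <- vapply(2:length(planted),
                       function(i) planted[sample.int(i - 1L, 1L)],
                       character(1))
      edges <- rbind(edges, data.frame(from = planted[-1L], to = anchor,
                                       stringsAsFactors = FALSE))
    }
    # canonicalize: undirected, simple
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    keep <- !duplicated(paste(a, b)) & a != b
    edges <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
    # connectivity repair
    g2 <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = ids))
    comp <- igraph::components(g2)
    if (comp$no > 1) {
      main <- which.max(comp$csize)
      main_anchor <- min(ids[comp$membership == main])
      others <- setdiff(seq_len(comp$no), main)
      bridges <- vapply(others, function(ci) min(ids[comp$membership == ci]),
                        character(1))
      message("reconnected ", length(bridges),
              " isolated component(s) by bridging to ", main_anchor)
      edges <- rbind(edges,
                     data.frame(from = pmin(bridges, main_anchor),
                                to = pmax(bridges, main_anchor),
                                stringsAsFactors = FALSE))
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    p <- stats::runif(n)
    names(p) <- ids
    if (length(planted) > 0) {
      p[planted] <- stats::rbeta(length(planted), cfg$signal_beta_a, 1)
    }
    p <- pmax(p, 1e-300)   # keep p-values strictly inside (0, 1]
    list(nodes = data.frame(id = ids, p_value = unname(p),
                            stringsAsFactors = FALSE),
         edges = edges,
         truth = list(planted_nodes = planted))
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: pathway collection, candidate panel, and interaction
#' graph from one configuration, plus the combined truth labels.
#'
#' @param cfg A [sim_config()].
#' @return A list with `db`, `candidates`, `graph`, `truth` and `config`.
#' @export
simulate_study <- function(cfg) {
  db <- generate_pathway_db(cfg)
  cand <- generate_candidate_set(db, cfg)
  graph <- generate_scored_graph(cfg)
  list(db = db, candidates = cand$genes, graph = graph,
       truth = c(cand$truth, graph$truth), config = cfg)
}

#' Serialize a synthetic study to disk
#'
#' Writes the study in the package's interchange formats: `pathways.gmt`
#' (class label and ko in the description field), `candidates.tsv`,
#' `ppi_edges.tsv`, `ppi_nodes.tsv` and `truth.json`. Output is byte-stable
#' for a fixed configuration.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(study$db, file.path(dir, "pathways.gmt"))
  write_candidates(study$candidates, file.path(dir, "candidates.tsv"))
  write_scored_network(study$graph, file.path(dir, "ppi_edges.tsv"),
                       file.path(dir, "ppi_nodes.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
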