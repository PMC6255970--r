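#' Configuration for an end-to-end pipeline run
#'
#' Collects stage toggles, input paths and thresholds. Defaults follow the
#' analysis conventions of the emulated study: pathways need at least 3
#' candidate genes, cross-talk pairs at least 3 shared genes, enrichment is
#' called at FDR < 0.05, and both the pair selection and the subnetwork
#' scoring use FDR < 0.01. The full configuration (and the seed) is written
#' into every output directory for provenance.
#'
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param simulate Generate inputs synthetically (default) instead of reading
#'   them from `gmt_path`/`candidates_path`/`edges_path`/`pvalues_path`.
#' @param gmt_path,candidates_path,edges_path,pvalues_path Input files used
#'   when `simulate = FALSE`.
#' @param background_size Enrichment background universe; defaults to the
#'   simulated universe size, or the pathway universe of a supplied GMT.
#' @param min_genes Gene-count filter for pathways (default 3).
#' @param min_shared Shared-gene filter for pairs (default 3).
#' @param enrich_alpha Enrichment significance threshold (default 0.05).
#' @param pair_fdr Cross-talk edge selection FDR (default 0.01).
#' @param subnet_fdr FDR target for subnetwork node scoring (default 0.01).
#' @param top_fraction Optional top fraction of ranked edges to keep.
#' @param run_subnet,run_enrich Stage toggles.
#' @param seed Master seed (propagated into `sim` when simulating).
#'
#' @return A validated `run_config`.
#' @export
run_config <- function(sim = sim_config(seed = seed),
                       simulate = TRUE,
                       gmt_path = NULL, candidates_path = NULL,
                       edges_path = NULL, pvalues_path = NULL,
                       background_size = NULL,
                       min_genes = 3, min_shared = 3,
                       enrich_alpha = 0.05, pair_fdr = 0.01,
                       subnet_fdr = 0.01, top_fraction = NULL,
                       run_subnet = TRUE, run_enrich = TRUE,
                       seed = 1L) {
  stopifnot(min_genes >= 1, min_shared >= 1,
            enrich_alpha > 0, enrich_alpha <= 1,
            pair_fdr > 0, pair_fdr <= 1,
            subnet_fdr > 0, subnet_fdr < 1)
  if (!simulate) {
    need <- c(gmt_path, candidates_path)
    if (length(need) < 2) stop("`gmt_path` and `candidates_path` are required when not simulating")
    if (run_subnet && (is.null(edges_path) || is.null(pvalues_path))) {
      stop("`edges_path` and `pvalues_path` are required for the subnetwork stage")
    }
  }
  structure(list(sim = sim, simulate = simulate,
                 gmt_path = gmt_path, candidates_path = candidates_path,
                 edges_path = edges_path, pvalues_path = pvalues_path,
                 background_size = background_size,
                 min_genes = min_genes, min_shared = min_shared,
                 enrich_alpha = enrich_alpha, pair_fdr = pair_fdr,
                 subnet_fdr = subnet_fdr, top_fraction = top_fraction,
                 run_subnet = run_subnet, run_enrich = run_enrich,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full candidate-gene cross-talk pipeline
#'
#' Chains the stages in the analysis order: (optionally) simulate or read the
#' inputs; enrich the candidate panel against the pathway collection; build
#' the cross-talk network (restrict pathways to the candidate panel, apply the
#' gene-count and shared-gene filters, test pair overlaps, select edges);
#' extract the maximal-scoring subnetwork from the interaction graph. All
#' stage outputs, a machine-readable `summary.json` with the filter-count
#' cascade, and the exact configuration (`config.yaml`) are written to
#' `outdir`. Progress is logged to standard error; results go only to files
#' and the returned object.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with `enrichment`, `network`, `subnetwork`,
#'   `summary` and `outdir`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (cfg$simulate) {
      study <- simulate_study(cfg$sim)
      write_simulation(study, file.path(outdir, "inputs"))
      list(db = study$db, candidates = study$candidates, graph = study$graph,
           truth = study$truth,
           background = cfg$background_size %||% cfg$sim$n_genes)
    } else {
      db <- read_gmt(cfg$gmt_path)
      list(db = db,
           candidates = read_candidates(cfg$candidates_path),
           graph = if (cfg$run_subnet) {
             read_scored_network(cfg$edges_path, cfg$pvalues_path)
           },
           truth = NULL,
           background = cfg$background_size %||% length(pathway_universe(db)))
    }
  })

  enr <- if (cfg$run_enrich) {
    stage("enrich", {
      res <- enrich(inputs$candidates, inputs$db,
                    background_size = inputs$background,
                    alpha = cfg$enrich_alpha)
      utils::write.table(.format_sci(res), file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  ct <- stage("crosstalk", {
    db_cand <- restrict_pathways(inputs$db, inputs$candidates)
    db_flt <- filter_min_genes(db_cand, cfg$min_genes)
    cp <- crosstalk_pairs(db_flt, min_shared = cfg$min_shared)
    edges <- rank_and_select(cp$pairs, fdr_max = cfg$pair_fdr,
                             min_shared = cfg$min_shared,
                             top_fraction = cfg$top_fraction)
    net <- build_network(edges, cp$db)
    write_network(net, outdir)
    mod <- data.frame(
      functional_class = rep(names(net$modules), lengths(net$modules)),
      pathway = unlist(net$modules, use.names = FALSE)
    )
    utils::write.table(mod, file.path(outdir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(net = net, counts = list(
      pathways_in = length(inputs$db),
      pathways_with_candidates = length(db_cand),
      pathways_min_genes = length(db_flt),
      valid_pathways = length(cp$db),
      pairs = nrow(cp$pairs),
      selected_edges = nrow(edges)
    ))
  })

  sub <- if (cfg$run_subnet && !is.null(inputs$graph)) {
    stage("subnet", {
      fit <- fit_bum(inputs$graph$nodes$p_value)
      sg <- score_nodes(inputs$graph, fit, fdr = cfg$subnet_fdr)
      sn <- extract_subnetwork(sg)
      jsonlite::write_json(
        list(lambda = fit$lambda, a = fit$a, tau = sg$tau,
             log_likelihood = fit$log_likelihood,
             no_signal = fit$no_signal),
        file.path(outdir, "bum_fit.json"), auto_unbox = TRUE, digits = NA)
      memb <- sg$nodes[sg$nodes$id %in% sn$nodes, ]
      utils::write.table(.format_sci(memb),
                         file.path(outdir, "subnetwork_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(subnetwork = sn, fit = fit, tau = sg$tau)
    })
  }

  summary <- c(
    ct$counts,
    list(
      enriched_terms = if (!is.null(enr)) sum(enr$significant) else NA,
      network_nodes = ct$net$summary$n_nodes,
      network_edges = ct$net$summary$n_edges,
      avg_degree = ct$net$summary$avg_degree,
      avg_clustering = ct$net$summary$avg_clustering,
      major_modules = ct$net$summary$n_major_modules,
      subnetwork_size = if (!is.null(sub)) length(sub$subnetwork$nodes) else NA,
      subnetwork_score = if (!is.null(sub)) sub$subnetwork$total_score else NA,
      subnet_skipped = is.null(sub),
      seed = cfg$seed
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- cfg
  cfg_out$sim <- unclass(cfg_out$sim)
  yaml::write_yaml(unclass(cfg_out), file.path(outdir, "config.yaml"))
  invisible(list(enrichment = enr, network = ct$net,
                 subnetwork = if (!is.null(sub)) sub$subnetwork,
                 summary = summary, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
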