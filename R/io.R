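# Readers and writers for the interchange formats the pipeline touches:
# GMT gene sets (functional class and ko identifier carried in the
# description field as "class=<label>|ko=<id>", which keeps files valid for
# other GMT consumers), headered TSV tables, SIF and GraphML networks.
# Gene IDs are case-sensitive and never normalized.

.parse_gmt_desc <- function(desc) {
  fields <- strsplit(desc, "|", fixed = TRUE)[[1]]
  out <- list(class = "unclassified", ko = NA_character_)
  for (f in fields) {
    if (startsWith(f, "class=")) out$class <- sub("^class=", "", f)
    if (startsWith(f, "ko=")) out$ko <- sub("^ko=", "", f)
  }
  out
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member...`. The description field is
#' parsed for `class=<label>` (functional class) and `ko=<id>` tokens,
#' separated by `|`. Duplicate members within a set are deduplicated with a
#' warning; duplicate pathway names are an error.
#'
#' @param path GMT file path.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(pathway_db(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 tab-separated fields",
                 short[1], path))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  meta <- lapply(vapply(fields, `[[`, character(1), 2L), .parse_gmt_desc)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), integer(1)))
  if (ndup > 0) warning(ndup, " duplicate member gene(s) removed")
  sets <- lapply(sets, unique)
  names(sets) <- nm
  pathway_db(sets,
             classes = vapply(meta, `[[`, character(1), "class"),
             ko = vapply(meta, `[[`, character(1), "ko"))
}

#' Write a pathway collection as GMT
#'
#' @param db A [pathway_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(seq_len(length(db)), function(i) {
    desc <- paste0("class=", db$classes[i],
                   if (!is.na(db$ko[i])) paste0("|ko=", db$ko[i]) else "")
    paste(c(names(db)[i], desc, db$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate gene list
#'
#' Headered TSV whose first column holds gene IDs; remaining columns (e.g. a
#' category label) are ignored for the gene set. Duplicates are removed and
#' the final count reported.
#'
#' @param path TSV file path.
#' @return Character vector of unique gene IDs.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) {
    warning("no candidate genes in ", path)
    return(character(0))
  }
  genes <- tab[[1]]
  ndup <- sum(duplicated(genes))
  genes <- unique(genes)
  message(length(genes), " candidate gene(s) read",
          if (ndup > 0) paste0(" (", ndup, " duplicate(s) removed)") else "")
  genes
}

#' @rdname read_candidates
#' @param genes Character vector of gene IDs to write.
#' @export
write_candidates <- function(genes, path) {
  utils::write.table(data.frame(gene_id = genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction network with node p-values
#'
#' `edges_path` is a headered TSV with two (or three; the third, typically a
#' weight, is ignored) columns of node IDs; `pvalues_path` a headered TSV with
#' columns `id` (or first column) and `p_value`. Self-loops are dropped with a
#' warning, duplicate and reversed edges collapsed, and every edge endpoint
#' must have a p-value in (0, 1].
#'
#' @param edges_path Edge list TSV.
#' @param pvalues_path Node table TSV.
#' @return A list with `nodes` (`id`, `p_value`) and `edges` (`from`, `to`),
#'   ready for [fit_bum()] and [score_nodes()].
#' @export
read_scored_network <- function(edges_path, pvalues_path) {
  for (p in c(edges_path, pvalues_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  etab <- utils::read.delim(edges_path, header = TRUE, stringsAsFactors = FALSE)
  ntab <- utils::read.delim(pvalues_path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(etab) < 2) stop("edge table must have at least 2 columns")
  from <- as.character(etab[[1]]); to <- as.character(etab[[2]])
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b))
  edges <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  pcol <- if ("p_value" %in% names(ntab)) "p_value" else names(ntab)[2]
  nodes <- data.frame(id = as.character(ntab[[1]]),
                      p_value = as.numeric(ntab[[pcol]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node IDs in ", pvalues_path)
  bad <- is.na(nodes$p_value) | nodes$p_value <= 0 | nodes$p_value > 1
  if (any(bad)) {
    stop("p-value outside (0, 1] for node(s): ",
         paste(utils::head(nodes$id[bad], 5), collapse = ", "))
  }
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) without a p-value: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' @rdname read_scored_network
#' @param graph A list with `nodes` and `edges` (as returned by
#'   [generate_scored_graph()] or [read_scored_network()]).
#' @export
write_scored_network <- function(graph, edges_path, pvalues_path) {
  edges <- graph$edges[order(graph$edges$from, graph$edges$to), , drop = FALSE]
  edges$weight <- 1L
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$nodes[, c("id", "p_value")], pvalues_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges_path)
}

#' Export a cross-talk network to standard formats
#'
#' Writes any of: SIF (`nodeA<TAB>crosstalk<TAB>nodeB`, sorted line order),
#' GraphML (typed node and edge attributes, via igraph), and a TSV edge table
#' with the similarity and significance columns.
#'
#' @param net A `crosstalk_network` from [build_network()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @param name Basename for the output files.
#' @return Character vector of files written, invisibly.
#' @export
write_network <- function(net, dir, formats = c("sif", "graphml", "tsv"),
                          name = "crosstalk") {
  stopifnot(inherits(net, "crosstalk_network"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if ("sif" %in% formats) {
    f <- file.path(dir, paste0(name, ".sif"))
    lines <- if (nrow(net$edges) > 0) {
      sort(paste(net$edges$pathway_a, "crosstalk", net$edges$pathway_b,
                 sep = "\t"))
    } else character(0)
    writeLines(lines, f)
    written <- c(written, f)
  }
  if ("graphml" %in% formats) {
    f <- file.path(dir, paste0(name, ".graphml"))
    igraph::write_graph(net$graph, f, format = "graphml")
    written <- c(written, f)
  }
  if ("tsv" %in% formats) {
    f <- file.path(dir, paste0(name, "_edges.tsv"))
    utils::write.table(.format_sci(net$edges), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

# print-style formatting: scientific notation, 3 significant digits, matching
# how enrichment tools typically report p-values
.format_sci <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], 3)
  }
  df
}
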