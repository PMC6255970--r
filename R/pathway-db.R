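#' Pathway collection with functional-class labels
#'
#' A `pathway_db` holds named gene sets, one per pathway or term, each carrying
#' a functional-class label (the KEGG-style metabolic class, or a GO ontology
#' code) and an optional KEGG orthology pathway identifier (`ko` followed by
#' five digits).
#'
#' @param sets Named list of character vectors; each element is one pathway's
#'   member gene IDs. Names must be unique and every set nonempty.
#' @param classes Character vector of functional-class labels, one per pathway
#'   (recycled if length one). Defaults to `"unclassified"`.
#' @param ko Optional character vector of KEGG orthology pathway identifiers
#'   (`ko#####`), or `NA` where unknown.
#'
#' @return An object of class `pathway_db`.
#' @examples
#' db <- pathway_db(
#'   list(P1 = c("g1", "g2", "g3"), P2 = c("g2", "g3", "g4")),
#'   classes = c("Amino acid metabolism", "Carbohydrate metabolism")
#' )
#' length(db)
#' pathway_universe(db)
#' @export
pathway_db <- function(sets, classes = NULL, ko = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || anyNA(nm) || any(nm == ""))) {
    stop("every pathway must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate pathway names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0) && length(sets) > 0) {
    stop("empty gene sets are not allowed: ",
         paste(nm[lengths(sets) == 0], collapse = ", "))
  }
  if (is.null(classes)) classes <- rep("unclassified", length(sets))
  if (length(classes) == 1L) classes <- rep(classes, length(sets))
  stopifnot(length(classes) == length(sets))
  if (is.null(ko)) ko <- rep(NA_character_, length(sets))
  if (length(ko) != length(sets)) stop("`ko` must match the number of pathways")
  bad_ko <- !is.na(ko) & !grepl("^ko[0-9]{5}$", ko)
  if (any(bad_ko)) {
    stop("malformed KEGG orthology identifiers: ", paste(ko[bad_ko], collapse = ", "))
  }
  classes <- stats::setNames(as.character(classes), nm)
  ko <- stats::setNames(as.character(ko), nm)
  structure(list(sets = sets, classes = classes, ko = ko),
            class = "pathway_db")
}

#' @export
length.pathway_db <- function(x) length(x$sets)

#' @export
names.pathway_db <- function(x) names(x$sets)

#' @export
`[.pathway_db` <- function(x, i) {
  pathway_db(x$sets[i], classes = x$classes[i], ko = x$ko[i])
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, %d genes in universe\n",
              length(x), length(pathway_universe(x))))
  if (length(x) > 0) {
    sz <- lengths(x$sets)
    cat(sprintf("  set sizes: %d-%d (median %.0f)\n",
                min(sz), max(sz), stats::median(sz)))
    cat(sprintf("  classes: %s\n",
                paste(utils::head(sort(unique(x$classes)), 5), collapse = "; ")))
  }
  invisible(x)
}

#' Union of all member genes in a pathway collection
#'
#' @param db A [pathway_db()].
#' @return Sorted character vector of gene IDs covered by at least one pathway.
#' @export
pathway_universe <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  sort(unique(unlist(db$sets, use.names = FALSE)))
}

#' Per-pathway gene counts
#'
#' @param db A [pathway_db()].
#' @return Named integer vector of set sizes.
#' @export
pathway_sizes <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  lengths(db$sets)
}

#' Restrict a pathway collection to a gene subset
#'
#' Intersects every pathway with `genes` (typically the candidate panel, so
#' that cross-talk is computed over the genes the study actually observed).
#' Pathways left empty by the restriction are dropped.
#'
#' @param db A [pathway_db()].
#' @param genes Character vector of gene IDs to keep.
#' @return A restricted `pathway_db`.
#' @export
restrict_pathways <- function(db, genes) {
  stopifnot(inherits(db, "pathway_db"))
  genes <- unique(as.character(genes))
  sets <- lapply(db$sets, intersect, y = genes)
  keep <- lengths(sets) > 0
  if (!all(keep)) {
    message(sum(!keep), " pathway(s) dropped: no member genes in the restriction set")
  }
  pathway_db(sets[keep], classes = db$classes[keep], ko = db$ko[keep])
}
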