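#' Exact hypergeometric upper-tail probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the one-sided
#' (over-representation) Fisher's exact p-value for observing `k` or more
#' query genes inside a term of size `K`, with a query of size `n` drawn from a
#' background of `N` genes. The tail is accumulated from exact log-binomial
#' coefficients with a scaled summation, so magnitudes far below double
#' precision's comfortable range (enrichment p-values like 4e-44 are routine
#' for strong signals) are computed without normal approximation or underflow
#' in intermediate terms.
#'
#' @param k Overlap count(s), `0 <= k <= min(K, n)`.
#' @param K Term size(s) in the background.
#' @param n Query size(s).
#' @param N Background universe size(s).
#'
#' @return Numeric vector of upper-tail probabilities (arguments are recycled
#'   to a common length).
#' @examples
#' hypergeom_upper_tail(5, 10, 10, 100)
#' hypergeom_upper_tail(0, 10, 10, 100)  # always 1
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), len)
  K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len)
  N <- rep_len(as.numeric(N), len)
  if (anyNA(c(k, K, n, N))) stop("margins must not contain NA")
  if (any(c(k, K, n, N) %% 1 != 0) || any(c(K, n, N) < 0) || any(N == 0)) {
    stop("margins must be nonnegative integers with N > 0")
  }
  if (any(K > N) || any(n > N)) stop("inconsistent margins: need K <= N and n <= N")
  if (any(k < 0) || any(k > pmin(K, n))) {
    stop("inconsistent margins: need 0 <= k <= min(K, n)")
  }
  out <- numeric(len)
  key <- paste(K, n, N)
  for (grp in split(seq_len(len), key)) {
    Kg <- K[grp[1L]]; ng <- n[grp[1L]]; Ng <- N[grp[1L]]
    lo <- max(0, Kg + ng - Ng)
    hi <- min(Kg, ng)
    i <- lo:hi
    lpmf <- lchoose(Kg, i) + lchoose(Ng - Kg, ng - i) - lchoose(Ng, ng)
    m <- max(lpmf)
    # tail(k) = sum_{i >= k} pmf(i); scaled so the largest term is 1
    tail_scaled <- rev(cumsum(rev(exp(lpmf - m))))
    ltail <- m + log(tail_scaled)
    idx <- pmax(k[grp] - lo, 0) + 1L
    val <- exp(pmin(ltail[idx], 0))
    val[k[grp] <= lo] <- 1   # at or below the support floor the tail is exactly 1
    out[grp] <- val
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values by the BH step-up rule
#' `q_(i) = min_{j >= i} p_(j) * m / j` (capped at 1), where `m` is the total
#' number of tests in the family. `m_total` may exceed the number of supplied
#' p-values: this is how tests with zero observable signal (e.g. terms with no
#' query overlap, which are never reported but were still tested) are counted
#' in the correction.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param m_total Size of the test family; defaults to `length(p_values)` and
#'   must be at least that.
#'
#' @return Adjusted p-values, in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' bh_adjust(c(0.01, 0.02), m_total = 10)
#' @export
bh_adjust <- function(p_values, m_total = length(p_values)) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (m_total < length(p)) stop("`m_total` must be >= length(p_values)")
  o <- order(p)
  q <- p[o] * m_total / seq_along(p)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(length(p))
  out[o] <- q
  out
}

#' Over-representation analysis of a candidate gene set
#'
#' Tests every term in `db` for over-representation of `query` genes against a
#' background of `background_size` genes, using the exact hypergeometric upper
#' tail ([hypergeom_upper_tail()]). BH adjustment is applied separately within
#' each ontology/functional-class stratum, with the stratum's full term count
#' as the family size (terms with zero overlap are tested but not reported).
#'
#' @param query Character vector of candidate gene IDs (deduplicated).
#' @param db A [pathway_db()] of terms; the `classes` labels define the BH
#'   strata.
#' @param background_size Number of genes in the background universe `N`.
#' @param alpha Significance threshold applied to the adjusted p-value to set
#'   the `significant` flag (records are returned regardless).
#'
#' @return A data frame with one row per term with at least one query gene:
#'   `term_id`, `ontology`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_raw` (ties by `term_id`).
#' @examples
#' db <- pathway_db(list(A = c("g1", "g2", "g3"), B = c("g4", "g5", "g6")))
#' enrich(c("g1", "g2", "g9"), db, background_size = 100)
#' @export
enrich <- function(query, db, background_size, alpha = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  if (length(db) == 0) stop("`db` must contain at least one term")
  if (!is.numeric(background_size) || length(background_size) != 1 ||
      background_size < 1) {
    stop("`background_size` must be a single positive count")
  }
  query <- unique(as.character(query))
  n <- length(query)
  empty <- data.frame(
    term_id = character(0), ontology = character(0),
    k = integer(0), K = integer(0), n = integer(0), N = integer(0),
    p_raw = numeric(0), p_adj = numeric(0), significant = logical(0),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    warning("empty query: no enrichment computed")
    return(empty)
  }
  if (n > background_size) stop("query larger than the background universe")
  K <- lengths(db$sets)
  if (any(K > background_size)) {
    stop("term(s) larger than the background universe: ",
         paste(names(db)[K > background_size], collapse = ", "))
  }
  k <- vapply(db$sets, function(s) length(intersect(s, query)), integer(1))
  res <- data.frame(
    term_id = names(db), ontology = db$classes,
    k = as.integer(k), K = as.integer(K), n = n,
    N = as.integer(background_size),
    p_raw = hypergeom_upper_tail(k, K, n, background_size),
    stringsAsFactors = FALSE
  )
  res$p_adj <- NA_real_
  for (str in unique(res$ontology)) {
    in_str <- res$ontology == str
    hit <- in_str & res$k >= 1
    if (any(hit)) {
      res$p_adj[hit] <- bh_adjust(res$p_raw[hit], m_total = sum(in_str))
    }
  }
  res <- res[res$k >= 1, , drop = FALSE]
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res$significant <- res$p_adj < alpha
  if (nrow(res) == 0) empty else res
}
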