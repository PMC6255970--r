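#' Fit a beta-uniform mixture to p-values
#'
#' Models a p-value distribution as uniform noise plus Beta(a, 1) signal,
#' `f(x) = lambda + (1 - lambda) * a * x^(a - 1)` on (0, 1], and estimates
#' `(lambda, a)` by maximum likelihood with bounded L-BFGS-B from five fixed
#' starting points (the likelihood surface can be multimodal for weak signal,
#' so the best of the five fits is returned).
#'
#' The fraction of the fitted density attributable to signal is
#' `1 - pi0` with `pi0 = lambda + (1 - lambda) * a` (the mixture density's
#' value at x = 1, the conservative null bound). When that mass is essentially
#' zero the fit is flagged `no_signal`.
#'
#' @param p_values Numeric vector of at least 50 p-values in (0, 1].
#' @return A `bum_fit`: list with `lambda`, `a`, `log_likelihood`, `n_points`,
#'   `pi0`, `no_signal`.
#' @examples
#' set.seed(1)
#' p <- c(runif(800), rbeta(200, 0.2, 1))
#' fit_bum(p)
#' @export
fit_bum <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  if (length(p) < 50) stop("at least 50 p-values are required for a stable fit")
  lp <- log(p)
  nll <- function(par) {
    lambda <- par[1]; a <- par[2]
    -sum(log(lambda + (1 - lambda) * a * exp((a - 1) * lp)))
  }
  eps <- 1e-6
  starts <- list(c(0.5, 0.5), c(0.9, 0.3), c(0.1, 0.3), c(0.7, 0.1), c(0.3, 0.7))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, nll, method = "L-BFGS-B",
                        lower = c(eps, eps), upper = c(1 - eps, 1 - eps))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  lambda <- best$par[1]; a <- best$par[2]
  pi0 <- lambda + (1 - lambda) * a
  structure(list(lambda = lambda, a = a,
                 log_likelihood = -best$value,
                 n_points = length(p),
                 pi0 = min(pi0, 1),
                 no_signal = (1 - pi0) < 0.01),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf(
    "<bum_fit> lambda = %.4f, a = %.4f (pi0 = %.4f), logL = %.2f, n = %d%s\n",
    x$lambda, x$a, x$pi0, x$log_likelihood, x$n_points,
    if (x$no_signal) " [no signal]" else ""))
  invisible(x)
}

#' Convert an FDR target into a p-value score threshold
#'
#' Under the fitted mixture, the estimated FDR of declaring all p-values below
#' `x` significant is `pi0 * x / F(x)` with `F(x) = lambda*x + (1-lambda)*x^a`
#' (the mixture CDF) and `pi0 = lambda + (1-lambda)*a`. For `a < 1` this is
#' nondecreasing in `x`, so the largest `x` with estimated FDR at most `fdr`
#' is found by bisection (to 1e-10). Nodes with p-values below the returned
#' threshold tau receive positive scores.
#'
#' @param fit A [fit_bum()] result.
#' @param fdr Target false discovery rate in (0, 1).
#' @return The threshold tau in (0, 1].
#' @export
fdr_to_tau <- function(fit, fdr) {
  stopifnot(inherits(fit, "bum_fit"))
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr <= 0 || fdr >= 1) {
    stop("`fdr` must lie in (0, 1)")
  }
  est_fdr <- function(x) {
    fit$pi0 * x / (fit$lambda * x + (1 - fit$lambda) * x^fit$a)
  }
  lo <- 1e-12
  if (est_fdr(lo) > fdr) {
    warning("no threshold attains the requested FDR; returning the smallest supported tau")
    return(lo)
  }
  if (est_fdr(1) <= fdr) return(1)
  hi <- 1
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (est_fdr(mid) <= fdr) lo <- mid else hi <- mid
  }
  lo
}

#' Score graph nodes from p-values under a fitted mixture
#'
#' Assigns each node the score `s(p) = (a - 1) * (log p - log tau)`, which is
#' positive exactly when `p < tau` and strictly decreasing in p, and each edge
#' the distance `(s_max - s(u)) + (s_max - s(v))` where `s_max` is the largest
#' node score. Edge distances are nonnegative and smallest between
#' high-scoring endpoints, so a minimum spanning tree over them follows
#' high-scoring corridors of the network.
#'
#' @param graph A list with `nodes` (data frame: `id`, `p_value`) and `edges`
#'   (data frame: `from`, `to`), e.g. from [generate_scored_graph()] or
#'   [read_scored_network()].
#' @param fit A [fit_bum()] result.
#' @param fdr FDR target passed to [fdr_to_tau()] (default 0.01).
#' @return A `scored_graph`: list with `nodes` (`id`, `p_value`, `score`),
#'   `edges` (`from`, `to`, `dist`), `tau` and `fit`.
#' @export
score_nodes <- function(graph, fit, fdr = 0.01) {
  stopifnot(inherits(fit, "bum_fit"))
  nodes <- graph$nodes
  edges <- graph$edges
  if (is.null(nodes$p_value) || anyNA(nodes$p_value)) {
    bad <- if (is.null(nodes$p_value)) nodes$id else nodes$id[is.na(nodes$p_value)]
    stop("missing p-value for node(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  tau <- fdr_to_tau(fit, fdr)
  s <- (fit$a - 1) * (log(nodes$p_value) - log(tau))
  names(s) <- nodes$id
  smax <- max(s)
  out_nodes <- data.frame(id = nodes$id, p_value = nodes$p_value, score = s,
                          stringsAsFactors = FALSE, row.names = NULL)
  out_edges <- data.frame(
    from = edges$from, to = edges$to,
    dist = (smax - s[edges$from]) + (smax - s[edges$to]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(nodes = out_nodes, edges = out_edges, tau = tau, fit = fit),
            class = "scored_graph")
}

#' @export
print.scored_graph <- function(x, ...) {
  cat(sprintf("<scored_graph> %d nodes, %d edges, tau = %.3g (%d positive)\n",
              nrow(x$nodes), nrow(x$edges), x$tau, sum(x$nodes$score > 0)))
  invisible(x)
}
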