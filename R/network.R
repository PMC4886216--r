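#' Pearson correlation matrix over all samples
#'
#' Computes gene-gene Pearson correlations across every sample (controls and
#' all post-injury time points). Genes with zero variance are dropped with a
#' warning before computation.
#'
#' @param expr An \code{\link{expression_set}} with at least 3 samples.
#' @param genes Optional character vector restricting the genes used (e.g.
#'   the injured-vs-healthier selection); all must be present.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  if (ncol(expr$exprs) < 3L) stop("need at least 3 samples to correlate")
  x <- expr$exprs
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) stop("gene(s) absent from expression matrix: ",
                              paste(utils::head(missing, 5L), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before correlation")
    x <- x[v > 0, , drop = FALSE]
  }
  stats::cor(t(x))
}

new_weighted_network <- function(weights, beta, tau = 0, sign = NULL,
                                 provenance = list()) {
  structure(list(nodes = rownames(weights), weights = weights, beta = beta,
                 tau = tau, sign = sign, provenance = provenance),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- length(x$nodes)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("weighted_network:", n, "nodes,", ne, "edges with positive weight;",
      "beta =", x$beta, "tau =", x$tau, "\n")
  invisible(x)
}

#' Soft-threshold a correlation matrix into a weighted adjacency
#'
#' Unsigned soft thresholding: \code{a_ij = |r_ij|^beta} with the diagonal
#' set to zero, so that the paper-standard beta = 6 maps |r| = 0.8 to a
#' weight of 0.262144 (0.26 at two decimals).
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param beta Soft-threshold power, an integer >= 1.
#' @return A \code{weighted_network} with \code{tau = 0}; the sign of each
#'   correlation is retained for export.
#' @export
soft_threshold <- function(corr, beta = 6L) {
  if (beta < 1) stop("beta must be >= 1")
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)) ||
      any(abs(diag(corr) - 1) > 1e-8)) {
    stop("corr must be symmetric with unit diagonal")
  }
  a <- abs(corr)^beta
  diag(a) <- 0
  sgn <- sign(corr)
  diag(sgn) <- 0L
  new_weighted_network(a, beta = beta, tau = 0, sign = sgn,
                       provenance = list(op = "soft_threshold", beta = beta))
}

#' Filter network edges by a weight threshold
#'
#' Weights strictly below \code{tau} are set to zero; weights at or above
#' \code{tau} are retained exactly (edges "below" the threshold are removed,
#' the boundary is kept). Isolated nodes remain in the node list. The
#' operation is idempotent.
#'
#' @param net A \code{weighted_network}.
#' @param tau Threshold in [0, 1]; the package default 0.26 corresponds to
#'   the beta = 6 weight of |r| = 0.8 at two decimals.
#' @param r_threshold Alternative: filter on |r| >= r_threshold instead
#'   (equivalent to \code{tau = r_threshold^beta}); overrides \code{tau}.
#' @return A \code{weighted_network} with \code{tau} recorded.
#' @export
threshold_edges <- function(net, tau = 0.26, r_threshold = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.null(r_threshold)) tau <- r_threshold^net$beta
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  w <- net$weights
  w[w < tau] <- 0
  net$weights <- w
  net$tau <- tau
  net$provenance <- c(net$provenance, list(tau = tau))
  net
}

#' Weighted connectivity of every node
#'
#' \code{k_i = sum_j a_ij} over the retained edges (weights below a recorded
#' threshold are already zero).
#'
#' @param net A \code{weighted_network}.
#' @return Named numeric vector of connectivities.
#' @export
weighted_connectivity <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  rowSums(net$weights)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the node connectivities into \code{n_bins} equal-width bins, then
#' regresses log10(mean frequency) on log10(mean connectivity) per non-empty
#' bin. A high R-squared indicates a power-law-like (scale-free) topology.
#'
#' @param net A \code{weighted_network} with >= 10 nodes.
#' @param n_bins Number of connectivity bins (default 10).
#' @return List with \code{r2}, \code{slope}, \code{n_bins_used}.
#' @export
scale_free_fit <- function(net, n_bins = 10L) {
  stopifnot(inherits(net, "weighted_network"))
  if (length(net$nodes) < 10L) stop("need at least 10 nodes for a scale-free fit")
  scale_free_fit_k(weighted_connectivity(net), n_bins = n_bins)
}

#' @rdname scale_free_fit
#' @param k Numeric vector of node connectivities (the workhorse interface,
#'   also usable on a constructed degree sequence).
#' @export
scale_free_fit_k <- function(k, n_bins = 10L) {
  if (max(k) - min(k) < .Machine$double.eps^0.5) {
    warning("all connectivities equal; scale-free R2 undefined, reported as 0")
    return(list(r2 = 0, slope = NA_real_, n_bins_used = 0L))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- as.vector(table(bins)) / length(k)
  mk <- as.vector(tapply(k, bins, mean))
  keep <- !is.na(mk) & freq > 0 & mk > 0
  if (sum(keep) < 3L) stop("fewer than 3 non-empty connectivity bins; fit undefined")
  fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       n_bins_used = sum(keep))
}

#' Topological summary statistics of a weighted network
#'
#' Density is the mean off-diagonal weight, heterogeneity the coefficient of
#' variation sd(k)/mean(k) of the node connectivities, and \code{n_edges}
#' counts pairs with weight >= tau (positive weight when unthresholded).
#'
#' @param net A \code{weighted_network} with >= 2 nodes.
#' @return A list of class \code{network_stats}.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- length(net$nodes)
  if (n < 2L) stop("need at least 2 nodes")
  w <- net$weights
  up <- w[upper.tri(w)]
  k <- rowSums(w)
  thr <- if (net$tau > 0) net$tau else .Machine$double.eps
  sf <- tryCatch(scale_free_fit(net),
                 error = function(e) list(r2 = NA_real_, slope = NA_real_))
  structure(list(
    n_nodes = n,
    n_edges = sum(up >= thr),
    density = mean(up),
    heterogeneity = if (mean(k) > 0) stats::sd(k) / mean(k) else NA_real_,
    median_connectivity = stats::median(k),
    scale_free_r2 = sf$r2,
    scale_free_slope = sf$slope,
    tau = net$tau
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("network_stats: %d nodes, %d edges (tau = %g)\n",
                     "  density = %.4g, heterogeneity = %.4g, median k = %.4g\n",
                     "  scale-free R2 = %.3f (slope %.3f)\n"),
              x$n_nodes, x$n_edges, x$tau, x$density, x$heterogeneity,
              x$median_connectivity, x$scale_free_r2, x$scale_free_slope))
  invisible(x)
}

#' Diagnostic sweep over soft-threshold powers
#'
#' Reports, for each power, the scale-free fit, median connectivity and the
#' modularity Q of a weighted Louvain partition of the thresholded network.
#' Purely diagnostic: nothing is auto-selected and the pipeline default
#' remains beta = 6.
#'
#' @param corr Correlation matrix.
#' @param betas Powers to evaluate.
#' @param tau Weight threshold applied before the modularity computation.
#' @return Data frame with one row per power.
#' @export
sweep_soft_threshold <- function(corr, betas = 1:12, tau = 0.26) {
  rows <- lapply(betas, function(b) {
    net <- soft_threshold(corr, beta = b)
    sf <- tryCatch(scale_free_fit(net),
                   error = function(e) list(r2 = NA_real_, slope = NA_real_))
    k <- weighted_connectivity(net)
    thr <- threshold_edges(net, tau = tau)
    g <- igraph_from_network(thr)
    q <- if (igraph::ecount(g) > 0) {
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      igraph::modularity(cl)
    } else NA_real_
    data.frame(beta = b, scale_free_r2 = sf$r2, slope = sf$slope,
               median_connectivity = stats::median(k), modularity = q)
  })
  do.call(rbind, rows)
}

# internal: igraph view of the retained edges (all nodes kept)
igraph_from_network <- function(net) {
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]))
    igraph::E(g)$weight <- w[idx]
  }
  g
}
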