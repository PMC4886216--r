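#' Permutation test for hub genes on weighted connectivity
#'
#' Tests, per gene, whether its weighted connectivity
#' \code{k_i = sum_j a_ij} over the retained edges is larger than expected
#' under a null in which the multiset of retained edge weights is randomly
#' reassigned to the fixed edge set (topology preserved, weights shuffled).
#' The empirical p-value uses the add-one convention
#' \code{p_i = (1 + #permutations with k_perm >= k_obs) / (B + 1)}, so the
#' smallest attainable p is \code{1/(B+1)}. P-values are BH-adjusted across
#' genes and hubs are flagged at adjusted p < \code{alpha}. The test is
#' one-sided: hubs are defined by excess connectivity only.
#'
#' A degree-preserving edge-rewiring null is available as an alternative
#' (\code{null = "degree-rewire"}): the topology is rewired keeping the
#' degree sequence and the observed weights are reassigned to the rewired
#' edges.
#'
#' @param net A thresholded \code{weighted_network} (\code{tau > 0}).
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param null Null model, \code{"weight-shuffle"} (default) or
#'   \code{"degree-rewire"}.
#' @param alpha Hub significance level on the adjusted p-value.
#' @return A \code{hub_result}: data frame with columns \code{gene},
#'   \code{k}, \code{degree}, \code{p}, \code{fdr}, \code{hub}; attributes
#'   \code{B}, \code{seed}, \code{null}, \code{alpha}.
#' @export
permutation_hub_test <- function(net, B = 1000L, seed = 1L,
                                 null = c("weight-shuffle", "degree-rewire"),
                                 alpha = 0.05) {
  stopifnot(inherits(net, "weighted_network"))
  null <- match.arg(null)
  if (B < 100L) stop("B must be >= 100")
  if (net$tau <= 0) stop("permutation_hub_test needs a thresholded network (tau > 0)")
  W <- net$weights
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  k_obs <- rowSums(W)
  degree <- rowSums(W > 0)
  if (nrow(idx) == 0L) {
    warning("empty edge set; all p-values are 1")
    res <- data.frame(gene = rownames(W), k = k_obs, degree = degree,
                      p = 1, fdr = 1, hub = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE)
    return(structure(res, B = B, seed = seed, null = null, alpha = alpha,
                     class = c("hub_result", "data.frame")))
  }
  w <- W[idx]
  E <- length(w)
  ends <- c(idx[, 1L], idx[, 2L])
  present <- sort(unique(ends))
  tol <- 1e-8
  counts <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(B)) {
      if (null == "weight-shuffle") {
        wp <- w[sample.int(E)]
        kp <- numeric(n)
        kp[present] <- rowsum(c(wp, wp), ends)[, 1L]
      } else {
        g <- igraph::make_empty_graph(n = n, directed = FALSE)
        g <- igraph::add_edges(g, as.vector(rbind(idx[, 1L], idx[, 2L])))
        g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * E))
        el <- igraph::as_edgelist(g, names = FALSE)
        kp <- numeric(n)
        kp[sort(unique(c(el)))] <- rowsum(c(w, w), c(el[, 1L], el[, 2L]))[, 1L]
      }
      counts <- counts + (kp >= k_obs - tol)
    }
  })
  p <- (1 + counts) / (B + 1)
  fdr <- bh_adjust(p)
  res <- data.frame(gene = rownames(W), k = k_obs, degree = degree,
                    p = p, fdr = fdr, hub = fdr < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, B = B, seed = seed, null = null, alpha = alpha,
            class = c("hub_result", "data.frame"))
}

#' @export
print.hub_result <- function(x, ...) {
  cat("hub_result:", nrow(x), "genes,", sum(x$hub), "hubs",
      sprintf("(B = %d, null = %s, alpha = %g)\n",
              attr(x, "B"), attr(x, "null"), attr(x, "alpha")))
  top <- x[order(x$p, -x$k), ]
  print.data.frame(utils::head(as.data.frame(top), 6L))
  invisible(x)
}
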