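#' Topological overlap matrix
#'
#' Unsigned topological overlap of a weighted network:
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with a unit diagonal. Shared neighbourhoods raise the overlap beyond the
#' direct connection strength, making 1 - TOM a robust clustering
#' dissimilarity.
#'
#' @param net A \code{weighted_network} (thresholded or not) with weights in
#'   [0, 1].
#' @return Symmetric matrix with entries in [0, 1] and unit diagonal.
#' @export
topological_overlap <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  a <- net$weights
  if (any(a < 0) || any(a > 1)) stop("weights must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

new_module_set <- function(method, modules, unassigned = character(),
                           params = list(), logs = NULL) {
  structure(list(method = method, modules = modules, unassigned = unassigned,
                 params = params, logs = logs),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set (", x$method, "): ", length(x$modules), " modules\n", sep = "")
  for (m in x$modules) {
    cat(sprintf("  %s: %d genes\n", m$id, length(m$genes)))
  }
  if (length(x$unassigned)) cat("  unassigned:", length(x$unassigned), "genes\n")
  invisible(x)
}

#' Gene sets of a module set
#'
#' @param ms A \code{module_set}.
#' @return Named list of gene-id vectors, one per module.
#' @export
module_genes <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  stats::setNames(lapply(ms$modules, `[[`, "genes"),
                  vapply(ms$modules, `[[`, character(1L), "id"))
}

#' Module eigengene
#'
#' First principal component of the row-standardized module submatrix,
#' sign-oriented so that it correlates non-negatively with the module's mean
#' standardized profile. Serves as the module's representative trajectory.
#'
#' @param expr An \code{\link{expression_set}}.
#' @param genes At least 2 gene ids present in \code{expr}.
#' @return List with \code{eigengene} (per-sample vector) and
#'   \code{variance_explained} in [0, 1].
#' @export
module_eigengene <- function(expr, genes) {
  stopifnot(inherits(expr, "expr_set"))
  if (length(genes) < 2L) stop("a module eigengene needs at least 2 genes")
  missing <- setdiff(genes, rownames(expr$exprs))
  if (length(missing)) stop("gene(s) absent from expression matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  x <- expr$exprs[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) stop("constant gene profile(s) in module; eigengene undefined")
  xs <- (x - rowMeans(x)) / sds
  sv <- svd(xs)
  eig <- sv$v[, 1L]
  ve <- sv$d[1L]^2 / sum(sv$d^2)
  ref <- colMeans(xs)
  if (stats::sd(ref) > 0 && stats::sd(eig) > 0) {
    cc <- stats::cor(eig, ref)
    if (!is.na(cc) && cc < 0) eig <- -eig
  }
  names(eig) <- colnames(expr$exprs)
  list(eigengene = eig, variance_explained = ve)
}

#' Hierarchical topological-overlap module detection
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM with
#' a static cut. By default the cut height is chosen adaptively as the
#' largest height at which the number of clusters of size >= \code{min_size}
#' is maximal (a deterministic scan over the dendrogram's merge heights);
#' a fixed \code{cut_height} can be supplied instead. Clusters smaller than
#' \code{min_size} are sent to the unassigned pool, weakly attached genes
#' are pruned by their module-eigengene correlation, and modules whose
#' eigengenes correlate above \code{merge_threshold} are merged iteratively.
#' Module ids follow the "1A, 2A, ..." convention in decreasing size order.
#'
#' @param tom Topological overlap matrix, genes in dimnames.
#' @param expr Expression set over the same genes (used for eigengenes).
#' @param cut_height Static cut height on 1 - TOM; \code{NULL} (default)
#'   selects it adaptively as described above.
#' @param min_size Minimum module size (>= 2).
#' @param merge_threshold Eigengene correlation above which modules merge;
#'   values > 1 disable merging.
#' @param kme_prune Module-membership pruning: after cutting, genes whose
#'   correlation with their module's eigengene falls below this value are
#'   moved to the unassigned pool (0 disables). Weakly attached genes
#'   otherwise chain onto modules under average linkage.
#' @return A \code{module_set} with method \code{"hierarchical-TOM"}.
#' @export
detect_modules_hierarchical <- function(tom, expr, cut_height = NULL,
                                        min_size = 30L, merge_threshold = 0.85,
                                        kme_prune = 0.7) {
  if (min_size < 2L) stop("min_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes) || !all(genes %in% rownames(expr$exprs))) {
    stop("tom and expr must cover the same genes")
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    # adaptive static cut: scan the midpoints between consecutive merge
    # heights, count clusters of size >= min_size, keep the largest height
    # attaining the maximal count
    hs <- sort(unique(hc$height))
    cand <- c((hs[-length(hs)] + hs[-1L]) / 2, hs[length(hs)] + 1e-6)
    n_valid <- vapply(cand, function(h) {
      sum(table(stats::cutree(hc, h = h)) >= min_size)
    }, integer(1L))
    best <- which(n_valid == max(n_valid))
    cut_height <- cand[best[length(best)]]
  }
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  unassigned <- genes[!labels %in% as.integer(keep)]
  groups <- lapply(keep, function(l) genes[labels == as.integer(l)])

  if (kme_prune > 0 && length(groups)) {
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      if (length(g) < 2L) next
      eig <- module_eigengene(expr, g)$eigengene
      kme <- abs(stats::cor(t(expr$exprs[g, , drop = FALSE]), eig)[, 1L])
      drop <- g[kme < kme_prune]
      if (length(drop)) {
        groups[[i]] <- setdiff(g, drop)
        unassigned <- c(unassigned, drop)
      }
    }
    small <- lengths(groups) < min_size
    unassigned <- c(unassigned, unlist(groups[small]))
    groups <- groups[!small]
  }

  if (length(groups) >= 2L && merge_threshold <= 1) {
    repeat {
      eigs <- vapply(groups, function(g) module_eigengene(expr, g)$eigengene,
                     numeric(ncol(expr$exprs)))
      cc <- stats::cor(eigs)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      if (cc[mx[1L], mx[2L]] <= merge_threshold) break
      groups[[mx[1L]]] <- c(groups[[mx[1L]]], groups[[mx[2L]]])
      groups[[mx[2L]]] <- NULL
      if (length(groups) < 2L) break
    }
  }

  ord <- order(-vapply(groups, length, integer(1L)))
  groups <- groups[ord]
  modules <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    eg <- module_eigengene(expr, g)
    list(id = paste0(i, "A"), genes = g,
         stats = list(size = length(g),
                      variance_explained = eg$variance_explained))
  })
  new_module_set("hierarchical-TOM", modules, unassigned = unassigned,
                 params = list(cut_height = unname(cut_height),
                               min_size = min_size,
                               merge_threshold = merge_threshold))
}

# cohesiveness of a vertex set: w_in / (w_in + w_out + penalty * |V|)
cohesiveness_score <- function(w_in, w_out, size, penalty) {
  den <- w_in + w_out + penalty * size
  if (den <= 0) 0 else w_in / den
}

#' Cohesiveness-based overlapping module detection
#'
#' Greedy growth in the style of overlapping neighbourhood expansion: seeds
#' are taken in decreasing weighted-connectivity order (ties broken by gene
#' id); from each uncovered seed a cluster is grown by single add/remove
#' steps that maximize the cohesiveness
#' \code{f(V) = w_in / (w_in + w_out + penalty |V|)} until no step improves
#' it. Candidate clusters with pairwise overlap score
#' \code{|A\eqn{\cap}B|^2 / (|A| |B|) >= overlap_merge} are merged
#' (transitively), clusters below \code{min_size} or \code{min_density} are
#' discarded, and each surviving cluster is tested by a one-sided
#' Mann-Whitney comparison of its members' in-cluster versus out-of-cluster
#' weight sums (BH-adjusted across clusters, kept at adjusted p < alpha).
#' Ids follow the "1B, 2B, ..." convention in decreasing size order.
#'
#' @param net A thresholded \code{weighted_network} (\code{tau > 0}).
#' @param penalty Size penalty p of the cohesiveness score.
#' @param min_size Minimum cluster size.
#' @param min_density Minimum internal edge density
#'   \code{w_in / (|V| (|V|-1) / 2)}.
#' @param overlap_merge Overlap-score threshold for merging.
#' @param alpha Significance level on the BH-adjusted cluster p-values.
#' @return A \code{module_set} with method \code{"cohesiveness"}; the
#'   per-seed cohesiveness step logs are kept in \code{$logs}.
#' @export
detect_modules_clusterone <- function(net, penalty = 2, min_size = 5L,
                                      min_density = 0.3, overlap_merge = 0.8,
                                      alpha = 0.05) {
  stopifnot(inherits(net, "weighted_network"))
  if (net$tau <= 0) stop("detect_modules_clusterone needs a thresholded network (tau > 0)")
  W <- net$weights
  n <- nrow(W)
  deg <- rowSums(W)
  if (all(deg == 0)) {
    warning("empty edge list; no cohesive modules")
    return(new_module_set("cohesiveness", list(),
                          params = list(penalty = penalty, min_size = min_size,
                                        min_density = min_density,
                                        overlap_merge = overlap_merge,
                                        alpha = alpha)))
  }
  ord <- order(-deg, rownames(W))
  covered <- rep(FALSE, n)
  clusters <- list()
  logs <- list()

  for (s in ord) {
    if (covered[s] || deg[s] == 0) next
    V <- logical(n); V[s] <- TRUE
    wtoV <- W[, s]
    w_in <- 0; w_out <- deg[s]
    fcur <- cohesiveness_score(w_in, w_out, 1L, penalty)
    flog <- fcur
    repeat {
      size <- sum(V)
      best_f <- fcur + 1e-12
      best <- NULL
      for (u in which(!V & wtoV > 0)) {
        fn <- cohesiveness_score(w_in + wtoV[u],
                                 w_out - wtoV[u] + (deg[u] - wtoV[u]),
                                 size + 1L, penalty)
        if (fn > best_f) { best_f <- fn; best <- c(u, 1L) }
      }
      if (size > 1L) {
        for (u in which(V)) {
          fn <- cohesiveness_score(w_in - wtoV[u],
                                   w_out + wtoV[u] - (deg[u] - wtoV[u]),
                                   size - 1L, penalty)
          if (fn > best_f) { best_f <- fn; best <- c(u, -1L) }
        }
      }
      if (is.null(best)) break
      u <- best[1L]
      if (best[2L] == 1L) {
        V[u] <- TRUE
        w_in <- w_in + wtoV[u]
        w_out <- w_out - wtoV[u] + (deg[u] - wtoV[u])
        wtoV <- wtoV + W[, u]
      } else {
        V[u] <- FALSE
        wtoV <- wtoV - W[, u]
        w_in <- w_in - wtoV[u]
        w_out <- w_out + wtoV[u] - (deg[u] - wtoV[u])
      }
      fcur <- best_f
      flog <- c(flog, fcur)
    }
    members <- which(V)
    covered[members] <- TRUE
    key <- paste(members, collapse = ",")
    if (!key %in% names(clusters)) {
      clusters[[key]] <- members
      logs[[key]] <- flog
    }
  }

  # transitive merge of strongly overlapping candidates
  if (length(clusters) >= 2L) {
    m <- length(clusters)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      ov <- length(intersect(clusters[[i]], clusters[[j]]))
      if (ov == 0L) next
      score <- ov^2 / (length(clusters[[i]]) * length(clusters[[j]]))
      if (score >= overlap_merge) parent[find(j)] <- find(i)
    }
    roots <- vapply(seq_len(m), find, integer(1L))
    clusters <- lapply(split(seq_len(m), roots), function(ix) {
      sort(unique(unlist(clusters[ix])))
    })
  }

  # size / density filters
  keep <- vapply(clusters, function(v) {
    sz <- length(v)
    if (sz < min_size) return(FALSE)
    w_in <- sum(W[v, v]) / 2
    w_in / (sz * (sz - 1) / 2) >= min_density
  }, logical(1L))
  clusters <- clusters[keep]

  # one-sided Mann-Whitney significance per cluster, BH across clusters
  if (length(clusters)) {
    pvals <- vapply(clusters, function(v) {
      in_sum <- rowSums(W[v, v, drop = FALSE])
      out_sum <- deg[v] - in_sum
      stats::wilcox.test(in_sum, out_sum, alternative = "greater",
                         exact = FALSE)$p.value
    }, numeric(1L))
    adj <- bh_adjust(pvals)
    clusters <- clusters[adj < alpha]
    adj <- adj[adj < alpha]
  } else {
    adj <- numeric(0)
  }

  ord2 <- order(-vapply(clusters, length, integer(1L)))
  clusters <- clusters[ord2]
  adj <- adj[ord2]
  modules <- lapply(seq_along(clusters), function(i) {
    v <- clusters[[i]]
    w_in <- sum(W[v, v]) / 2
    list(id = paste0(i, "B"), genes = rownames(W)[v],
         stats = list(size = length(v),
                      density = w_in / (length(v) * (length(v) - 1) / 2),
                      adjusted_p = unname(adj[i])))
  })
  new_module_set("cohesiveness", modules,
                 params = list(penalty = penalty, min_size = min_size,
                               min_density = min_density,
                               overlap_merge = overlap_merge, alpha = alpha),
                 logs = unname(logs))
}

#' Jaccard comparison of two module catalogs
#'
#' \code{J(A, B) = |A intersect B| / |A union B|} for every pair of modules;
#' the best-matching pair is reported as an attribute.
#'
#' @param setA,setB Non-empty \code{module_set}s (or named lists of gene
#'   vectors).
#' @return Matrix of Jaccard coefficients (rows = \code{setA} modules) with
#'   attribute \code{best} = list(idA, idB, jaccard).
#' @export
compare_modules_jaccard <- function(setA, setB) {
  la <- if (inherits(setA, "module_set")) module_genes(setA) else setA
  lb <- if (inherits(setB, "module_set")) module_genes(setB) else setB
  if (!length(la) || !length(lb)) stop("both module sets must be non-empty")
  J <- matrix(0, length(la), length(lb), dimnames = list(names(la), names(lb)))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    J[i, j] <- length(intersect(la[[i]], lb[[j]])) /
      length(union(la[[i]], lb[[j]]))
  }
  mx <- which(J == max(J), arr.ind = TRUE)[1L, ]
  attr(J, "best") <- list(idA = rownames(J)[mx[1L]], idB = colnames(J)[mx[2L]],
                          jaccard = max(J))
  J
}
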