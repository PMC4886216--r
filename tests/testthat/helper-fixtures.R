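# shared fixtures and independent brute-force oracles

# small expression set built directly from a matrix
make_expr <- function(mat, groups) {
  expression_set(mat, data.frame(
    sample = colnames(mat), group = groups,
    replicate = stats::ave(seq_along(groups), groups, FUN = seq_along)))
}

# weighted network straight from a weight matrix
make_net <- function(w, beta = 6, tau = 0) {
  regenet:::new_weighted_network(w, beta = beta, tau = tau)
}

# minimal hub_result for the cross-species operations
fake_hub_result <- function(genes, hub) {
  structure(data.frame(gene = genes, k = as.numeric(hub), degree = 1L,
                       p = ifelse(hub, 0.001, 0.5),
                       fdr = ifelse(hub, 0.01, 0.5), hub = hub,
                       stringsAsFactors = FALSE),
            B = 1000L, seed = 1L, null = "weight-shuffle", alpha = 0.05,
            class = c("hub_result", "data.frame"))
}

# minimal sim_truth for the companion-table generators
fake_truth <- function(n_genes, hub_idx = integer(0)) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  module_of <- stats::setNames(integer(n_genes), genes)
  is_hub <- stats::setNames(logical(n_genes), genes)
  is_hub[hub_idx] <- TRUE
  structure(list(module_of = module_of, is_de = is_hub, is_hub = is_hub,
                 effect_trajectories = matrix(0, n_genes, 1,
                                              dimnames = list(genes, "4hpi")),
                 latent_trajectories = matrix(0, 3, 0),
                 hub_secondary = integer(n_genes)),
            class = "sim_truth")
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force topological overlap (triple loop)
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# hypergeometric upper tail by exhaustive enumeration over overlap counts
hyper_oracle <- function(overlap, term_size, module_size, universe) {
  ks <- overlap:min(term_size, module_size)
  sum(choose(term_size, ks) * choose(universe - term_size, module_size - ks)) /
    choose(universe, module_size)
}

# Pearson chi-square on a 2x2, closed form, no continuity correction
chisq_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  n <- sum(tab)
  n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# mean best-match Jaccard of the planted modules against a detected catalog
jaccard_vs_truth <- function(ms, truth) {
  tm <- split(names(truth$module_of)[truth$module_of > 0],
              truth$module_of[truth$module_of > 0])
  dm <- module_genes(ms)
  if (!length(dm)) return(0)
  vapply(tm, function(g) {
    max(vapply(dm, function(d) {
      length(intersect(g, d)) / length(union(g, d))
    }, numeric(1)))
  }, numeric(1))
}

# the two contrast schemes of the regeneration design
injured_groups <- c("4hpi", "1dpi", "3dpi", "7dpi", "14dpi")
healthier_groups <- c("control", "90dpi")
ivh_contrast <- function() de_contrast("injured_vs_healthier",
                                       injured_groups, healthier_groups)
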