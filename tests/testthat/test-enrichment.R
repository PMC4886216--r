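test_that("hypergeometric enrichment matches hand enumeration", {
  # universe 20, module 5, term 8, overlap 4:
  # p = [C(8,4) C(12,1) + C(8,5) C(12,0)] / C(20,5) = 896/15504
  universe <- paste0("g", 1:20)
  mods <- list(m1 = c("g1", "g2", "g3", "g4", "g9"))
  ann <- structure(list(t1 = paste0("g", 1:8)), class = "annotation_table")
  res <- hypergeometric_enrichment(mods, ann, universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p, 896 / 15504, tolerance = 1e-12)

  # a term equal to the universe is uninformative
  ann2 <- structure(list(all = universe), class = "annotation_table")
  res2 <- hypergeometric_enrichment(mods, ann2, universe)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  expect_error(hypergeometric_enrichment(mods, ann, character(0)), "universe")
  expect_error(hypergeometric_enrichment(list(m1 = "zz"), ann, universe),
               "outside the universe")
})

test_that("hypergeometric p matches exhaustive enumeration on random instances", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(10:25, 1)
    universe <- paste0("g", seq_len(N))
    msize <- sample(2:(N - 2), 1)
    tsize <- sample(2:(N - 2), 1)
    mods <- list(m = sample(universe, msize))
    ann <- structure(list(t = sample(universe, tsize)),
                     class = "annotation_table")
    res <- hypergeometric_enrichment(mods, ann, universe)
    if (nrow(res) == 0) next
    expect_equal(res$p, hyper_oracle(res$overlap, tsize, msize, N),
                 tolerance = 1e-12)
    expect_lte(res$overlap, min(msize, tsize))
  }
})

test_that("strongly enriched synthetic annotations surface their module first", {
  sim <- simulate_timecourse(sim_config(n_genes = 500, n_modules = 2,
                                        module_sizes = c(50, 50),
                                        n_planted_hubs = 0, seed = 14))
  ann <- simulate_annotations(sim$truth, n_terms = 20, enrichment_odds = 50,
                              seed = 4)
  mods <- split(names(sim$truth$module_of)[sim$truth$module_of > 0],
                sim$truth$module_of[sim$truth$module_of > 0])
  names(mods) <- c("m1", "m2")
  res <- hypergeometric_enrichment(mods, ann, names(sim$truth$module_of))
  top <- res[which.min(res$fdr), ]
  # the smallest FDR belongs to a designated (module, term) pair:
  # odd terms target module 1, even terms module 2
  designated_module <- ifelse(as.integer(sub("term", "", top$term)) %% 2 == 1,
                              "m1", "m2")
  expect_equal(top$module, designated_module)
  expect_true(top$significant)
})

test_that("conservation chi-square matches the closed form and is label-symmetric", {
  genes <- paste0("g", 1:1000)
  hub <- c(rep(TRUE, 100), rep(FALSE, 900))
  orth_genes <- c(genes[1:80], genes[101:700])  # 80/100 hubs, 600/900 non-hubs
  orthology <- data.frame(gene = orth_genes, species = "human",
                          ortholog = toupper(orth_genes), source = "ZFIN")
  hr <- fake_hub_result(genes, hub)
  ct <- conservation_chisq(hr, orthology, "human")
  tab <- matrix(c(80, 600, 20, 300), 2, 2)
  expect_equal(ct$statistic, chisq_oracle(tab), tolerance = 1e-10)
  expect_equal(ct$statistic, 7.3529, tolerance = 1e-3)
  expect_equal(ct$hub_fraction, 0.8)
  # swapping rows/columns leaves the statistic unchanged
  expect_equal(chisq_oracle(tab), chisq_oracle(tab[2:1, ]), tolerance = 1e-12)
  expect_equal(chisq_oracle(tab), chisq_oracle(t(tab)), tolerance = 1e-12)

  # equal proportions give a null statistic
  orth_eq <- data.frame(gene = c(genes[1:50], genes[101:550]),
                        species = "human",
                        ortholog = "X", source = "ZFIN")
  expect_equal(conservation_chisq(hr, orth_eq, "human")$statistic, 0,
               tolerance = 1e-10)

  # zero margin is reported as undefined, not an error
  hr_none <- fake_hub_result(genes, rep(FALSE, 1000))
  ct0 <- conservation_chisq(hr_none, orthology, "human")
  expect_true(is.na(ct0$statistic))
  expect_match(ct0$note, "margin")
})

test_that("chi-square p agrees with a Monte-Carlo permutation of hub labels", {
  set.seed(20)
  genes <- paste0("g", 1:2000)
  hub <- c(rep(TRUE, 500), rep(FALSE, 1500))
  has_orth <- c(stats::runif(500) < 0.57, stats::runif(1500) < 0.50)
  orthology <- data.frame(gene = genes[has_orth], species = "human",
                          ortholog = toupper(genes[has_orth]), source = "ZFIN")
  hr <- fake_hub_result(genes, hub)
  ct <- suppressMessages(conservation_chisq(hr, orthology, "human"))
  B <- 10000
  n_hub <- sum(hub)
  stat_perm <- vapply(seq_len(B), function(b) {
    sh <- sample(hub)
    n11 <- sum(sh & has_orth)
    chisq_oracle(matrix(c(n11, sum(has_orth) - n11,
                          n_hub - n11,
                          sum(!has_orth) - (n_hub - n11)), 2, 2))
  }, numeric(1))
  # mid-p counting: the permutation statistic is discrete, the chi-square
  # reference continuous, so the observed atom is split
  p_mc <- mean(stat_perm > ct$statistic + 1e-9) +
    0.5 * mean(abs(stat_perm - ct$statistic) < 1e-9)
  mc_sd <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p_mc - ct$p), 2 * mc_sd)
})

test_that("miR-target mapping joins through orthology and de-duplicates", {
  genes <- c("fam49ba", "il6st", "gata4", "tbx5a")
  hr <- fake_hub_result(genes, c(TRUE, TRUE, TRUE, FALSE))
  orthology <- data.frame(
    gene = c("fam49ba", "il6st", "tbx5a"),
    species = "human",
    ortholog = c("FAM49B", "IL6ST", "TBX5"),
    source = "Homologene")
  mir_table <- data.frame(
    mir = c("hsa-miR-590-3p", "hsa-miR-590-3p", "hsa-miR-590-3p", "hsa-miR-1"),
    target = c("FAM49B", "IL6ST", "IL6ST", "TBX5"),
    species = "human",
    evidence = c("validated", "validated", "predicted", "validated"))
  out <- map_mir_targets(hr, orthology, mir_table, species = "human")
  # two hubs validated for one miR; duplicates collapse; non-hub excluded;
  # gata4 has no ortholog so contributes nothing
  expect_equal(nrow(out), 2L)
  expect_equal(unname(attr(out, "summary")["validated"]), 2L)
  expect_setequal(out$hub, c("fam49ba", "il6st"))
  expect_false("tbx5a" %in% out$hub)
  # the validated record outranks the duplicated predicted one
  expect_true(all(out$evidence == "validated"))
  # whitelist restriction and unknown species
  out2 <- map_mir_targets(hr, orthology, mir_table, species = "human",
                          mir_whitelist = "hsa-miR-1")
  expect_equal(nrow(out2), 0L)
  expect_error(map_mir_targets(hr, orthology, mir_table, species = "dog"),
               "unknown species")
  # row-count bound
  expect_lte(nrow(out), sum(hr$hub) * length(unique(mir_table$mir)) * 1)
})
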