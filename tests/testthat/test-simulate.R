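test_that("simulation is deterministic given the seed, for all three generators", {
  cf <- sim_config(n_genes = 200, n_modules = 2, module_sizes = c(20, 20),
                   n_planted_hubs = 4, seed = 11)
  a <- simulate_timecourse(cf)
  b <- simulate_timecourse(cf)
  expect_identical(a$expr$exprs, b$expr$exprs)
  expect_identical(a$truth$module_of, b$truth$module_of)
  ann1 <- simulate_annotations(a$truth, n_terms = 10, seed = 3)
  ann2 <- simulate_annotations(a$truth, n_terms = 10, seed = 3)
  expect_identical(unclass(ann1), unclass(ann2))
  xs1 <- simulate_crossspecies(a$truth, seed = 5)
  xs2 <- simulate_crossspecies(a$truth, seed = 5)
  expect_identical(xs1, xs2)
})

test_that("a noise-free module forces perfect within-module correlation", {
  cf <- sim_config(n_genes = 3, n_modules = 1, module_sizes = 3,
                   de_fraction = 0, noise_sd = 0, n_planted_hubs = 0, seed = 2)
  sim <- simulate_timecourse(cf)
  r <- stats::cor(t(sim$expr$exprs))
  expect_true(all(abs(r - 1) < 1e-12))
})

test_that("the global null yields uniform moderated-t p-values", {
  cf <- sim_config(n_genes = 2000, n_modules = 0, module_sizes = integer(0),
                   de_fraction = 0, n_planted_hubs = 0, seed = 5)
  sim <- simulate_timecourse(cf)
  de <- moderated_t_test(sim$expr, ivh_contrast())
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 100, module_sizes = rep(60, 5)),
               "exceed")
  expect_error(sim_config(effect_decay = c("4hpi" = 1, "1dpi" = 0.9,
                                           "3dpi" = 0.95, "7dpi" = 0.5,
                                           "14dpi" = 0.25, "90dpi" = 0)),
               "non-increasing")
  expect_error(sim_config(effect_decay = c("4hpi" = 1, "1dpi" = 0.9,
                                           "3dpi" = 0.7, "7dpi" = 0.5,
                                           "14dpi" = 0.25, "90dpi" = 0.5)))
  expect_error(sim_config(de_fraction = 1.2), "proportions")
  expect_error(sim_config(n_modules = 0, module_sizes = integer(0),
                          n_planted_hubs = 5), "module")
})

test_that("planted hubs live in planted modules and null genes have zero trajectories", {
  sim <- simulate_timecourse(sim_config(n_genes = 400, n_modules = 3,
                                        module_sizes = rep(30, 3),
                                        n_planted_hubs = 6, seed = 8))
  tr <- sim$truth
  expect_true(all(tr$module_of[tr$is_hub] > 0))
  null_rows <- tr$effect_trajectories[!tr$is_de, , drop = FALSE]
  expect_true(all(null_rows == 0))
  de_rows <- tr$effect_trajectories[tr$is_de, , drop = FALSE]
  expect_true(all(rowSums(abs(de_rows)) > 0))
})

test_that("within-module correlation rises monotonically with its target", {
  means <- vapply(c(0.5, 0.7, 0.9), function(w) {
    sim <- simulate_timecourse(sim_config(n_genes = 40, n_modules = 1,
                                          module_sizes = 40, de_fraction = 0,
                                          within_module_correlation = w,
                                          n_planted_hubs = 0, seed = 4))
    r <- stats::cor(t(sim$expr$exprs))
    mean(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("per-time DEG counts decline over the regeneration time course", {
  times <- c(injured_groups, "90dpi")
  rhos <- vapply(1:20, function(sd) {
    sim <- simulate_timecourse(sim_config(n_genes = 300, n_modules = 2,
                                          module_sizes = c(25, 25),
                                          de_fraction = 0.4, effect_size = 1.5,
                                          n_planted_hubs = 0, seed = sd))
    counts <- vapply(times, function(g) {
      sum(moderated_t_test(sim$expr, de_contrast(g, g, "control"))$fdr < 0.05)
    }, numeric(1))
    suppressWarnings(stats::cor(seq_along(times), counts, method = "spearman"))
  }, numeric(1))
  # sign test: declining counts in nearly every replicate
  expect_gte(sum(rhos < 0), 18)
})

test_that("annotation terms honor the GMT contract and the enrichment odds", {
  sim <- simulate_timecourse(sim_config(n_genes = 300, n_modules = 2,
                                        module_sizes = c(50, 50),
                                        n_planted_hubs = 0, seed = 6))
  ann <- simulate_annotations(sim$truth, n_terms = 10, seed = 1)
  expect_length(ann, 10)
  expect_true(all(lengths(ann) >= 1))
  expect_error(simulate_annotations(sim$truth, n_terms = 0), "n_terms")
  # infinite odds with term size = module size gives complete overlap
  annI <- simulate_annotations(sim$truth, n_terms = 1, enrichment_odds = Inf,
                               seed = 2, term_size_range = c(50, 50))
  mod1 <- names(sim$truth$module_of)[sim$truth$module_of == 1]
  expect_setequal(annI[[1]], mod1)
})

test_that("neutral annotation odds give uniform hypergeometric enrichment", {
  sim <- simulate_timecourse(sim_config(seed = 9))
  ann <- simulate_annotations(sim$truth, n_terms = 200, enrichment_odds = 1,
                              seed = 7)
  mods <- split(names(sim$truth$module_of)[sim$truth$module_of > 0],
                sim$truth$module_of[sim$truth$module_of > 0])
  names(mods) <- paste0("m", names(mods))
  res <- hypergeometric_enrichment(mods, ann,
                                   universe = names(sim$truth$module_of))
  frac <- sum(res$p < 0.05) / (length(mods) * length(ann))
  band <- 3 * sqrt(0.05 * 0.95 / (length(mods) * length(ann)))
  # the discrete hypergeometric p is super-uniform: never anti-conservative,
  # but well above zero under neutral odds
  expect_lt(frac, 0.05 + band)
  expect_gt(frac, 0.005)
})

test_that("conservation chi-square is calibrated when hubs are not special", {
  truth <- fake_truth(400, hub_idx = 1:80)
  rej <- vapply(1:500, function(sd) {
    xs <- simulate_crossspecies(
      truth, ortholog_rates = list(human = c(hub = 0.5, nonhub = 0.5)),
      mir_config = NULL, seed = sd)
    hr <- fake_hub_result(names(truth$is_hub), truth$is_hub)
    ct <- suppressMessages(conservation_chisq(hr, xs$orthology, "human"))
    !is.na(ct$p) && ct$p < 0.05
  }, logical(1))
  band <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), band)
})

test_that("conservation chi-square has power at the study's hub scale", {
  truth <- fake_truth(3467, hub_idx = 1:425)
  hr <- fake_hub_result(names(truth$is_hub), truth$is_hub)
  sig <- vapply(1:500, function(sd) {
    xs <- simulate_crossspecies(
      truth, ortholog_rates = list(mouse = c(hub = 0.79, nonhub = 0.50)),
      mir_config = NULL, seed = sd)
    ct <- suppressMessages(conservation_chisq(hr, xs$orthology, "mouse"))
    ct$p < 0.001
  }, logical(1))
  expect_gt(mean(sig), 0.99)
})

test_that("an empty miR configuration yields an empty target table", {
  truth <- fake_truth(50, hub_idx = 1:5)
  xs <- simulate_crossspecies(
    truth, ortholog_rates = list(human = c(hub = 1, nonhub = 0.5)),
    mir_config = list(species = "human", mirs = "hsa-miR-1",
                      n_validated = 0, n_predicted = 0, n_background = 0),
    seed = 1)
  expect_equal(nrow(xs$mir_targets), 0)
  expect_error(
    simulate_crossspecies(truth,
                          ortholog_rates = list(human = c(hub = 1, nonhub = 0.5)),
                          mir_config = list(species = "dog", mirs = "x",
                                            n_validated = 1, n_predicted = 1),
                          seed = 1),
    "unknown species")
})
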