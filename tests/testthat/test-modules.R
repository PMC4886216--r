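test_that("topological overlap matches the defining formula and its oracle", {
  # triangle with all weights 0.5: TOM = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  dimnames(w) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- topological_overlap(make_net(w))
  expect_equal(tom["g1", "g2"], 0.5, tolerance = 1e-12)
  expect_true(all(diag(tom) == 1))

  # two nodes joined by weight 1, no other neighbours
  w2 <- matrix(0, 2, 2); w2[1, 2] <- w2[2, 1] <- 1
  dimnames(w2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(topological_overlap(make_net(w2))["a", "b"], 1)

  # brute-force agreement on random instances
  set.seed(7)
  for (i in 1:25) {
    n <- sample(8:15, 1)
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2)
    a <- a + t(a)
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- topological_overlap(make_net(a))
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 - 1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
})

test_that("hierarchical detection recovers two perfect TOM blocks", {
  n <- 20
  tom <- matrix(0.05, n, n)
  tom[1:10, 1:10] <- 0.9
  tom[11:20, 11:20] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  set.seed(2)
  # expression with clearly distinct block profiles (no accidental merging)
  prof1 <- rnorm(21); prof2 <- rnorm(21)
  mat <- rbind(t(sapply(1:10, function(i) prof1 + rnorm(21, 0, 0.05))),
               t(sapply(1:10, function(i) prof2 + rnorm(21, 0, 0.05))))
  dimnames(mat) <- list(paste0("g", 1:n), paste0("s", 1:21))
  expr <- make_expr(mat, rep(c("control", injured_groups, "90dpi"), each = 3))
  ms <- detect_modules_hierarchical(tom, expr, min_size = 3)
  expect_length(ms$modules, 2L)
  expect_setequal(module_genes(ms)[["1A"]], paste0("g", 1:10))
  expect_setequal(module_genes(ms)[["2A"]], paste0("g", 11:20))
  expect_error(detect_modules_hierarchical(tom, expr, min_size = 1),
               "min_size")
})

test_that("eigengene merging is controlled by its threshold", {
  n <- 20
  tom <- matrix(0.05, n, n)
  tom[1:10, 1:10] <- 0.9
  tom[11:20, 11:20] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  set.seed(5)
  shared <- rnorm(21)
  mat <- t(sapply(1:n, function(i) shared + rnorm(21, 0, 0.1)))
  dimnames(mat) <- list(paste0("g", 1:n), paste0("s", 1:21))
  expr <- make_expr(mat, rep(c("control", injured_groups, "90dpi"), each = 3))
  # nearly identical eigengenes: default merges, merge-off limit does not
  merged <- detect_modules_hierarchical(tom, expr, min_size = 3,
                                        merge_threshold = 0.85)
  expect_length(merged$modules, 1L)
  apart <- detect_modules_hierarchical(tom, expr, min_size = 3,
                                       merge_threshold = 1 + 1e-9)
  expect_length(apart$modules, 2L)
})

test_that("hierarchical modules partition the node set", {
  sim <- simulate_timecourse(sim_config(n_genes = 400, n_modules = 3,
                                        module_sizes = rep(40, 3), seed = 31))
  net <- soft_threshold(correlation_matrix(sim$expr), 6)
  tom <- topological_overlap(net)
  ms <- detect_modules_hierarchical(tom, sim$expr, min_size = 10)
  all_assigned <- unlist(module_genes(ms), use.names = FALSE)
  expect_equal(anyDuplicated(all_assigned), 0L)
  expect_setequal(c(all_assigned, ms$unassigned), rownames(tom))
})

test_that("module eigengene honours its variance and orientation contracts", {
  mat <- matrix(rep(c(1, 3, 2, 5, 4, 6), each = 4), 4, 6, byrow = FALSE)
  dimnames(mat) <- list(paste0("g", 1:4), paste0("s", 1:6))
  expr <- make_expr(mat, rep(c("control", "4hpi"), each = 3))
  eg <- module_eigengene(expr, paste0("g", 1:4))
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  xs <- t(scale(t(mat)))
  expect_gte(stats::cor(eg$eigengene, colMeans(xs)), 0)

  flat <- rbind(mat, g5 = rep(1, 6))
  exprf <- make_expr(flat, rep(c("control", "4hpi"), each = 3))
  expect_error(module_eigengene(exprf, c("g1", "g5")), "constant")
  expect_error(module_eigengene(expr, "g1"), "at least 2")

  # round trip: noise-free module eigengene recovers the latent trajectory
  sim <- simulate_timecourse(sim_config(n_genes = 10, n_modules = 1,
                                        module_sizes = 10, de_fraction = 0,
                                        noise_sd = 0, n_planted_hubs = 0,
                                        seed = 3))
  eg2 <- module_eigengene(sim$expr, rownames(sim$expr$exprs))
  lat <- sim$truth$latent_trajectories[, 1]
  expect_gte(abs(stats::cor(eg2$eigengene, lat)), 0.999)
})

test_that("cohesiveness scoring and greedy growth behave as specified", {
  expect_equal(regenet:::cohesiveness_score(6, 2, 4, 0), 0.75)
  expect_equal(regenet:::cohesiveness_score(6, 2, 4, 2),
               6 / (6 + 2 + 8))

  # two 6-cliques joined by a weak edge are recovered separately
  n <- 12
  w <- matrix(0, n, n)
  w[1:6, 1:6] <- 1; w[7:12, 7:12] <- 1; diag(w) <- 0
  w[6, 7] <- w[7, 6] <- 0.1
  dimnames(w) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  ms <- detect_modules_clusterone(make_net(w, tau = 0.05), penalty = 0,
                                  min_size = 3, min_density = 0.3)
  got <- module_genes(ms)
  expect_length(got, 2L)
  expect_setequal(got[[1]], sprintf("g%02d", 1:6))
  expect_setequal(got[[2]], sprintf("g%02d", 7:12))

  # each clique is a local optimum of the cohesiveness score
  f_of <- function(v) {
    w_in <- sum(w[v, v]) / 2
    w_out <- sum(w[v, setdiff(1:n, v)])
    regenet:::cohesiveness_score(w_in, w_out, length(v), 0)
  }
  clique <- 1:6
  f0 <- f_of(clique)
  for (u in 7:12) expect_lt(f_of(c(clique, u)), f0)
  for (u in clique) expect_lt(f_of(setdiff(clique, u)), f0)

  # an isolated clique is a fixed point
  w2 <- matrix(1, 5, 5); diag(w2) <- 0
  dimnames(w2) <- list(paste0("g", 1:5), paste0("g", 1:5))
  ms2 <- detect_modules_clusterone(make_net(w2, tau = 0.5), penalty = 1,
                                   min_size = 3, min_density = 0.3)
  expect_length(ms2$modules, 1L)
  expect_setequal(module_genes(ms2)[[1]], paste0("g", 1:5))

  # growth never decreases the cohesiveness along accepted steps
  for (log in ms$logs) expect_true(all(diff(log) > 0))

  # empty edge list
  w0 <- matrix(0, 4, 4)
  dimnames(w0) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_warning(ms0 <- detect_modules_clusterone(make_net(w0, tau = 0.1)),
                 "empty")
  expect_length(ms0$modules, 0L)
  expect_error(detect_modules_clusterone(make_net(w2, tau = 0)), "tau")
})

test_that("planted modules are recovered by both detectors", {
  sim <- simulate_timecourse(sim_config(n_genes = 500, n_modules = 3,
                                        module_sizes = rep(40, 3),
                                        n_planted_hubs = 6, seed = 19))
  net <- soft_threshold(correlation_matrix(sim$expr,
                                           names(sim$truth$module_of)[sim$truth$module_of > 0]),
                        6)
  tom <- topological_overlap(net)
  mh <- detect_modules_hierarchical(tom, sim$expr, min_size = 10)
  expect_gte(mean(jaccard_vs_truth(mh, sim$truth)), 0.8)
  mc <- detect_modules_clusterone(threshold_edges(net, 0.26), min_size = 5)
  expect_gte(mean(jaccard_vs_truth(mc, sim$truth)), 0.8)
})

test_that("module catalogs compare by symmetric Jaccard coefficients", {
  a <- list(m1 = paste0("g", 1:10), m2 = paste0("g", 11:20))
  b <- list(x1 = paste0("g", 1:10), x2 = paste0("g", c(6:10, 21:25)),
            x3 = paste0("g", 30:35))
  J <- compare_modules_jaccard(a, b)
  expect_equal(J["m1", "x1"], 1)
  expect_equal(J["m2", "x3"], 0)
  expect_equal(J["m1", "x2"], 5 / 15, tolerance = 1e-12)
  Jt <- compare_modules_jaccard(b, a)
  expect_equal(J, t(Jt), ignore_attr = TRUE)
  expect_equal(attr(J, "best")$jaccard, 1)
  expect_equal(attr(J, "best")$idA, "m1")
  expect_error(compare_modules_jaccard(list(), a), "non-empty")
})
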