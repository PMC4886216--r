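#' Configuration for the synthetic regeneration time course
#'
#' Defines the study design emulated by \code{\link{simulate_timecourse}}:
#' seven condition groups (uninjured controls, 4 hours post-injury, then 1, 3,
#' 7, 14 and 90 days post-injury) measured in triplicate, a majority of null
#' genes, injury-responsive genes whose effects are largest early and vanish
#' by 90 dpi, K planted co-expression modules driven by latent trajectories,
#' and a minority of planted high-connectivity (hub) genes.
#'
#' Module member genes follow \code{baseline + loading * latent + noise};
#' the latent trajectory of each module mixes a group-level injury response
#' (a decaying bump peaking at a module-specific time point; fraction
#' \code{latent_group_share} of latent variance) with per-sample variation.
#' \code{within_module_correlation} sets the expected pairwise Pearson
#' correlation between members. Planted hubs load on two module trajectories
#' (variance shares \code{hub_primary_share} and \code{hub_secondary_share})
#' with little idiosyncratic noise, so their edges carry systematically larger
#' weights than ordinary member-member edges and their realized connectivity
#' exceeds background. Injury-responsive background genes shift by
#' \code{effect_size * effect_decay[group]} with random sign.
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted modules K (0 allowed: a global null).
#' @param module_sizes Integer vector of K module sizes; must sum to at most
#'   \code{n_genes}.
#' @param groups Ordered condition labels; the first is the control group.
#' @param n_replicates Replicates per group.
#' @param de_fraction Proportion of genes that are injury-responsive
#'   (module members count towards this fraction).
#' @param effect_decay Named per-group effect multipliers for the injured
#'   groups, monotone non-increasing from 4 hpi to 90 dpi with the 90 dpi
#'   value at most 0.1 times the 4 hpi value.
#' @param effect_size Log2 shift of injury-responsive background genes at a
#'   decay multiplier of 1.
#' @param within_module_correlation Target pairwise correlation within a
#'   module, in (0, 1).
#' @param latent_group_share Fraction of each latent trajectory's variance
#'   carried by the group-level injury response, in [0, 1].
#' @param noise_sd Standard deviation of i.i.d. Gaussian gene-level noise.
#' @param n_planted_hubs Number of planted hub genes (each belongs to a
#'   planted module; requires K >= 1 when positive; K >= 2 gives hubs a
#'   distinct secondary module).
#' @param hub_primary_share,hub_secondary_share Variance shares of a hub's
#'   primary and secondary module latent.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_modules = 5L,
                       module_sizes = rep(60L, n_modules),
                       groups = c("control", "4hpi", "1dpi", "3dpi", "7dpi", "14dpi", "90dpi"),
                       n_replicates = 3L,
                       de_fraction = 0.20,
                       effect_decay = c("4hpi" = 1, "1dpi" = 0.9, "3dpi" = 0.7,
                                        "7dpi" = 0.5, "14dpi" = 0.25, "90dpi" = 0),
                       effect_size = 1.2,
                       within_module_correlation = 0.9,
                       latent_group_share = 0.95,
                       noise_sd = 0.5,
                       n_planted_hubs = 20L,
                       hub_primary_share = 0.99,
                       hub_secondary_share = 0.01,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  n_modules <- as.integer(n_modules)
  if (length(module_sizes) != n_modules) stop("module_sizes must have length n_modules")
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  if (n_modules > 0 && any(module_sizes < 2L)) stop("module sizes must be >= 2")
  if (length(groups) < 2L) stop("need a control group and at least one injured group")
  injured <- groups[-1L]
  if (!identical(sort(names(effect_decay)), sort(injured))) {
    stop("effect_decay must be named by the injured groups: ",
         paste(injured, collapse = ", "))
  }
  effect_decay <- effect_decay[injured]
  if (any(diff(effect_decay) > 1e-12)) stop("effect_decay must be monotone non-increasing")
  if (effect_decay[[length(effect_decay)]] > 0.1 * effect_decay[[1L]] + 1e-12) {
    stop("final-group effect multiplier must be <= 0.1 x the first injured group's")
  }
  for (p in list(de_fraction = de_fraction, latent_group_share = latent_group_share,
                 hub_primary_share = hub_primary_share,
                 hub_secondary_share = hub_secondary_share)) {
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  }
  if (hub_primary_share + hub_secondary_share > 1) {
    stop("hub variance shares must sum to at most 1")
  }
  if (within_module_correlation <= 0 || within_module_correlation >= 1) {
    stop("within_module_correlation must lie in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_planted_hubs > 0 && n_modules < 1L) stop("planted hubs require at least one module")
  if (n_planted_hubs > sum(module_sizes)) stop("more planted hubs than module genes")
  structure(list(
    n_genes = as.integer(n_genes), n_modules = n_modules, module_sizes = module_sizes,
    groups = groups, n_replicates = as.integer(n_replicates),
    de_fraction = de_fraction, effect_decay = effect_decay, effect_size = effect_size,
    within_module_correlation = within_module_correlation,
    latent_group_share = latent_group_share, noise_sd = noise_sd,
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_primary_share = hub_primary_share, hub_secondary_share = hub_secondary_share,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

# run code under a local RNG state so simulation calls do not disturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a regeneration expression time course with known ground truth
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{expr} (an \code{\link{expression_set}})
#'   and \code{truth} (class \code{sim_truth}): \code{module_of} (gene ->
#'   module id, 0 = background), \code{is_de}, \code{effect_trajectories}
#'   (genes x groups matrix of realized group-mean shifts relative to
#'   control; all-zero rows for non-responsive genes), \code{is_hub} and
#'   \code{latent_trajectories} (samples x K).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n_s <- length(cf$groups) * cf$n_replicates
    sample_group <- rep(cf$groups, each = cf$n_replicates)
    sample_ids <- paste0(sample_group, "_r", rep(seq_len(cf$n_replicates), length(cf$groups)))
    genes <- sprintf("gene%05d", seq_len(cf$n_genes))
    K <- cf$n_modules

    module_of <- integer(cf$n_genes)
    if (K > 0) {
      starts <- cumsum(c(1L, cf$module_sizes))
      for (m in seq_len(K)) {
        module_of[seq.int(starts[m], length.out = cf$module_sizes[m])] <- m
      }
    }
    names(module_of) <- genes

    is_hub <- logical(cf$n_genes)
    names(is_hub) <- genes
    hub_secondary <- integer(cf$n_genes)
    if (cf$n_planted_hubs > 0) {
      per_mod <- split(which(module_of > 0), module_of[module_of > 0])
      hub_idx <- integer(0)
      i <- 1L
      while (length(hub_idx) < cf$n_planted_hubs) {
        m <- ((i - 1L) %% K) + 1L
        pos <- ceiling(i / K)
        if (pos <= length(per_mod[[m]])) hub_idx <- c(hub_idx, per_mod[[m]][pos])
        i <- i + 1L
      }
      is_hub[hub_idx] <- TRUE
      hub_secondary[hub_idx] <- if (K >= 2) (module_of[hub_idx] %% K) + 1L else module_of[hub_idx]
    }

    # Module latent trajectories. Each module's injured-side profile is a
    # shared injury-response mean (mildly tilted towards the early, high-decay
    # time points) plus a module-specific peak-time contrast; control and the
    # fully regenerated group(s) sit at zero. The contrasts are centered
    # peak-group indicators (pairwise correlation -1/(R-1) over R responding
    # groups), so modules stay selectable in the injured-vs-healthier
    # contrast while remaining mutually separable in the network.
    injured <- names(cf$effect_decay)
    responding <- injured[cf$effect_decay > 0.1 * cf$effect_decay[[1L]]]
    if (!length(responding)) responding <- injured[1L]
    R <- length(responding)
    nd <- cf$effect_decay[responding] / mean(cf$effect_decay[responding])
    decay_tilt <- 0.3   # mild early emphasis of the shared response
    peak_weight <- 0.42 # sd of the module-specific peak contrast
    base_profile <- 1 + decay_tilt * (nd - 1)
    decay_of <- c(stats::setNames(0, cf$groups[1L]), cf$effect_decay)
    latents <- matrix(0, n_s, max(K, 1L))
    if (K > 0) {
      for (m in seq_len(K)) {
        peak <- responding[((m - 1L) %% R) + 1L]
        contrast <- (responding == peak) - 1 / R
        if (R > 1L) contrast <- contrast / stats::sd(contrast)
        profile <- stats::setNames(rep(0, length(cf$groups)), cf$groups)
        profile[responding] <- base_profile + peak_weight * contrast
        sgn <- if (m %% 2L == 1L) 1 else -1
        sv <- sgn * profile[sample_group]
        sv <- sv - mean(sv)
        if (stats::sd(sv) > 0) sv <- sv * sqrt(cf$latent_group_share) / stats::sd(sv)
        lat <- sv + stats::rnorm(n_s, 0, sqrt(max(0, 1 - cf$latent_group_share)))
        latents[, m] <- (lat - mean(lat)) / stats::sd(lat)
      }
      colnames(latents) <- paste0("module", seq_len(K))
      rownames(latents) <- sample_ids
    }

    loading <- if (cf$noise_sd == 0) 1 else {
      cf$noise_sd * sqrt(cf$within_module_correlation / (1 - cf$within_module_correlation))
    }
    v_tot <- loading^2 + cf$noise_sd^2

    baseline <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
    X <- matrix(stats::rnorm(cf$n_genes * n_s, 0, cf$noise_sd), cf$n_genes, n_s)

    for (g in which(module_of > 0 & !is_hub)) {
      X[g, ] <- X[g, ] + loading * latents[, module_of[g]]
    }
    for (g in which(is_hub)) {
      resid <- max(0, 1 - cf$hub_primary_share - cf$hub_secondary_share)
      X[g, ] <- sqrt(cf$hub_primary_share * v_tot) * latents[, module_of[g]] +
        sqrt(cf$hub_secondary_share * v_tot) * latents[, hub_secondary[g]] +
        sqrt(resid * v_tot) * stats::rnorm(n_s)
    }

    # injury-responsive background genes: signed, decaying shift
    is_de <- module_of > 0
    n_bg_de <- max(0L, round(cf$de_fraction * cf$n_genes) - sum(is_de))
    bg <- which(module_of == 0)
    de_sign <- numeric(cf$n_genes)
    if (n_bg_de > 0 && length(bg)) {
      de_bg <- sample(bg, min(n_bg_de, length(bg)))
      de_sign[de_bg] <- sample(c(-1, 1), length(de_bg), replace = TRUE)
      shift <- cf$effect_size * decay_of[sample_group]
      for (g in de_bg) X[g, ] <- X[g, ] + de_sign[g] * shift
      is_de[de_bg] <- TRUE
    }
    names(is_de) <- genes

    X <- X + baseline
    dimnames(X) <- list(genes, sample_ids)

    # realized group-mean shifts relative to control, for truth bookkeeping
    eff <- matrix(0, cf$n_genes, length(cf$groups),
                  dimnames = list(genes, cf$groups))
    if (K > 0) {
      gm <- apply(latents, 2L, function(l) tapply(l, sample_group, mean)[cf$groups])
      gm <- sweep(gm, 2L, gm[1L, ], "-")
      for (g in which(module_of > 0 & !is_hub)) eff[g, ] <- loading * gm[, module_of[g]]
      for (g in which(is_hub)) {
        eff[g, ] <- sqrt(cf$hub_primary_share * v_tot) * gm[, module_of[g]] +
          sqrt(cf$hub_secondary_share * v_tot) * gm[, hub_secondary[g]]
      }
    }
    for (g in which(de_sign != 0)) {
      eff[g, ] <- eff[g, ] + de_sign[g] * cf$effect_size * decay_of[cf$groups]
    }
    eff[!is_de, ] <- 0

    meta <- data.frame(sample = sample_ids, group = sample_group,
                       replicate = rep(seq_len(cf$n_replicates), length(cf$groups)),
                       stringsAsFactors = FALSE)
    truth <- structure(list(
      module_of = module_of, is_de = is_de, is_hub = is_hub,
      effect_trajectories = eff,
      latent_trajectories = if (K > 0) latents else matrix(0, n_s, 0),
      hub_secondary = hub_secondary, config = cf
    ), class = "sim_truth")
    list(expr = expression_set(X, meta), truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$module_of), "genes,",
      max(0L, max(x$module_of)), "planted modules,",
      sum(x$is_hub), "planted hubs,", sum(x$is_de), "injury-responsive genes\n")
  invisible(x)
}

#' Simulate a GMT-style annotation table concentrated in planted modules
#'
#' Each term's genes are drawn without replacement with odds
#' \code{enrichment_odds} of coming from one designated module (terms cycle
#' through the planted modules). \code{enrichment_odds = 1} gives unstructured
#' terms; \code{Inf} draws entirely from the designated module.
#'
#' @param truth A \code{sim_truth} with at least one planted module.
#' @param n_terms Number of terms (>= 1).
#' @param enrichment_odds Odds ratio favouring the designated module.
#' @param seed Integer seed.
#' @param term_size_range Inclusive range of term sizes.
#' @return An \code{annotation_table}: a named list of gene vectors with a
#'   \code{description} attribute, one entry per term.
#' @export
simulate_annotations <- function(truth, n_terms, enrichment_odds = 1, seed = 1L,
                                 term_size_range = c(10L, 50L)) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_terms < 1L) stop("n_terms must be >= 1")
  K <- max(truth$module_of)
  if (K < 1L) stop("truth must contain at least one planted module")
  genes <- names(truth$module_of)
  with_seed(seed, {
    terms <- vector("list", n_terms)
    desc <- character(n_terms)
    sizes <- seq.int(term_size_range[1L], term_size_range[2L])
    for (t in seq_len(n_terms)) {
      m <- ((t - 1L) %% K) + 1L
      size <- sizes[sample.int(length(sizes), 1L)]
      in_mod <- truth$module_of == m
      if (is.infinite(enrichment_odds)) {
        size <- min(size, sum(in_mod))
        terms[[t]] <- sample(genes[in_mod], size)
      } else {
        w <- ifelse(in_mod, enrichment_odds, 1)
        terms[[t]] <- sample(genes, size, prob = w)
      }
      desc[t] <- sprintf("synthetic term %d (module %d, odds %s)", t, m,
                         format(enrichment_odds))
    }
    names(terms) <- sprintf("term%03d", seq_len(n_terms))
    structure(terms, description = stats::setNames(desc, names(terms)),
              class = "annotation_table")
  })
}

#' Simulate orthology and miR-target companion tables
#'
#' Each gene receives an ortholog per species by a Bernoulli draw whose rate
#' depends on whether the gene is a planted hub, emulating higher conservation
#' among hubs. The miR-target table links a configurable number of hub
#' orthologs (plus non-hub decoys) to named miRs with an evidence flag.
#'
#' @param truth A \code{sim_truth}.
#' @param ortholog_rates Named list, one entry per species, each a numeric
#'   vector with elements \code{hub} and \code{nonhub} in [0, 1].
#' @param mir_config List with elements \code{species}, \code{mirs}
#'   (character), \code{n_validated}, \code{n_predicted} and optionally
#'   \code{n_background} (rows targeting non-hub orthologs; default 20).
#' @param seed Integer seed.
#' @return A list with \code{orthology} (data frame: gene, species, ortholog,
#'   source) and \code{mir_targets} (data frame: mir, target, species,
#'   evidence).
#' @export
simulate_crossspecies <- function(truth,
                                  ortholog_rates = list(
                                    human = c(hub = 0.78, nonhub = 0.50),
                                    mouse = c(hub = 0.79, nonhub = 0.50),
                                    rat = c(hub = 0.78, nonhub = 0.50)),
                                  mir_config = list(
                                    species = "human",
                                    mirs = c("hsa-miR-590-3p", "hsa-miR-1",
                                             "hsa-miR-195", "hsa-miR-199a-3p"),
                                    n_validated = 2L, n_predicted = 18L),
                                  seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  for (sp in names(ortholog_rates)) {
    r <- ortholog_rates[[sp]]
    if (!all(c("hub", "nonhub") %in% names(r)) || any(r < 0) || any(r > 1)) {
      stop("ortholog_rates[['", sp, "']] needs elements 'hub' and 'nonhub' in [0, 1]")
    }
  }
  if (!is.null(mir_config) && !mir_config$species %in% names(ortholog_rates)) {
    stop("unknown species label in mir_config: ", mir_config$species)
  }
  genes <- names(truth$module_of)
  with_seed(seed, {
    orth <- do.call(rbind, lapply(names(ortholog_rates), function(sp) {
      r <- ortholog_rates[[sp]]
      rate <- ifelse(truth$is_hub, r[["hub"]], r[["nonhub"]])
      has <- stats::rbinom(length(genes), 1L, rate) == 1L
      if (!any(has)) return(NULL)
      data.frame(gene = genes[has], species = sp,
                 ortholog = paste0(toupper(genes[has]), "_", toupper(substr(sp, 1L, 2L))),
                 source = sample(c("ZFIN", "Homologene", "BLAST", "GeneCards"),
                                 sum(has), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(orth)) {
      orth <- data.frame(gene = character(), species = character(),
                         ortholog = character(), source = character())
    }
    mir <- data.frame(mir = character(), target = character(),
                      species = character(), evidence = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(mir_config)) {
      sp <- mir_config$species
      n_bg <- if (is.null(mir_config$n_background)) 20L else mir_config$n_background
      hub_orth <- orth$ortholog[orth$species == sp & truth$is_hub[orth$gene]]
      nonhub_orth <- orth$ortholog[orth$species == sp & !truth$is_hub[orth$gene]]
      draw <- function(pool, n, evidence) {
        n <- min(n, length(pool) * length(mir_config$mirs))
        if (n < 1L || !length(pool)) return(NULL)
        pairs <- expand.grid(mir = mir_config$mirs, target = pool,
                             stringsAsFactors = FALSE)
        pairs <- pairs[sample.int(nrow(pairs), n), , drop = FALSE]
        data.frame(pairs, species = sp, evidence = evidence,
                   stringsAsFactors = FALSE)
      }
      mir <- rbind(
        draw(hub_orth, mir_config$n_validated, "validated"),
        draw(hub_orth, mir_config$n_predicted, "predicted"),
        draw(nonhub_orth, n_bg, "predicted")
      )
      if (is.null(mir)) {
        mir <- data.frame(mir = character(), target = character(),
                          species = character(), evidence = character(),
                          stringsAsFactors = FALSE)
      }
      rownames(mir) <- NULL
    }
    list(orthology = orth, mir_targets = mir)
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth A \code{sim_truth}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    module_of = as.list(truth$module_of),
    is_de = as.list(truth$is_de),
    is_hub = as.list(truth$is_hub),
    latent_trajectories = truth$latent_trajectories,
    effect_trajectories = truth$effect_trajectories
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
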