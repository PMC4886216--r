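#' Configuration of the full co-expression pipeline
#'
#' Collects the inputs and the analysis thresholds: the gene-selection FDR
#' (default 0.005, injured-vs-healthier contrast), the per-time DEG FDR
#' (default 0.001), the soft-threshold power beta (default 6), the edge
#' weight threshold tau (default 0.26, the two-decimal weight of |r| = 0.8
#' at beta = 6; set \code{filter_on = "correlation"} to filter on
#' |r| >= 0.8 instead), the module-detection parameters of both algorithms,
#' the permutation count of the hub test and the enrichment significance
#' level.
#'
#' @param expr An \code{\link{expression_set}} or path to an expression TSV.
#' @param metadata Path to the sample-metadata TSV (when \code{expr} is a
#'   path).
#' @param probe_map Optional probe-to-gene data frame (or TSV path) enabling
#'   probe collapsing.
#' @param collapse_rule Probe collapse rule, see \code{\link{collapse_probes}}.
#' @param annotations Optional \code{annotation_table} or GMT path.
#' @param orthology Optional orthology data frame or TSV path.
#' @param mir_targets Optional miR-target data frame or TSV path.
#' @param control_group,regenerated_group Labels of the healthy reference
#'   groups (pooled into the "healthier" side of the selection contrast).
#' @param fdr_select FDR threshold of the gene-selection contrast.
#' @param fdr_pertime FDR threshold of the per-time contrasts.
#' @param beta Soft-threshold power.
#' @param tau Edge weight threshold.
#' @param filter_on \code{"weight"} (filter at \code{tau}) or
#'   \code{"correlation"} (filter at \code{|r| >= r_threshold}).
#' @param r_threshold Correlation threshold used when
#'   \code{filter_on = "correlation"}.
#' @param hier Named list of \code{\link{detect_modules_hierarchical}}
#'   overrides (cut_height, min_size, merge_threshold).
#' @param cohesive Named list of \code{\link{detect_modules_clusterone}}
#'   overrides (penalty, min_size, min_density, overlap_merge, alpha).
#' @param hub_B Permutation count of the hub test.
#' @param hub_null Null model of the hub test.
#' @param alpha_enrich Enrichment / conservation significance level.
#' @param species Species labels for conservation and miR mapping.
#' @param mir_whitelist Optional miR ids to restrict the mapping to.
#' @param seed Integer seed governing the hub permutations.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expr, metadata = NULL, probe_map = NULL,
                            collapse_rule = "max-variance",
                            annotations = NULL, orthology = NULL,
                            mir_targets = NULL,
                            control_group = "control",
                            regenerated_group = "90dpi",
                            fdr_select = 0.005, fdr_pertime = 0.001,
                            beta = 6L, tau = 0.26,
                            filter_on = c("weight", "correlation"),
                            r_threshold = 0.8,
                            hier = list(), cohesive = list(),
                            hub_B = 1000L,
                            hub_null = "weight-shuffle",
                            alpha_enrich = 0.05,
                            species = NULL, mir_whitelist = NULL,
                            seed = 1L) {
  filter_on <- match.arg(filter_on)
  for (thr in c(fdr_select, fdr_pertime, alpha_enrich)) {
    if (thr <= 0 || thr >= 1) stop("FDR / alpha thresholds must lie in (0, 1)")
  }
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (beta < 1) stop("beta must be >= 1")
  structure(list(expr = expr, metadata = metadata, probe_map = probe_map,
                 collapse_rule = collapse_rule, annotations = annotations,
                 orthology = orthology, mir_targets = mir_targets,
                 control_group = control_group,
                 regenerated_group = regenerated_group,
                 fdr_select = fdr_select, fdr_pertime = fdr_pertime,
                 beta = beta, tau = tau, filter_on = filter_on,
                 r_threshold = r_threshold, hier = hier, cohesive = cohesive,
                 hub_B = as.integer(hub_B), hub_null = hub_null,
                 alpha_enrich = alpha_enrich, species = species,
                 mir_whitelist = mir_whitelist, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full co-expression network pipeline
#'
#' Executes, in order: probe collapsing (if a probe map is given), per-time
#' and injured-vs-healthier moderated differential expression, gene
#' selection, Pearson correlation, soft thresholding, edge filtering, module
#' detection by both algorithms, Jaccard comparison of the two catalogs, the
#' permutation hub test, hypergeometric enrichment, conservation chi-square
#' tests and miR-target mapping (the last three only when the corresponding
#' tables are supplied). Every stage failure aborts with the stage name.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A list of class \code{regen_bundle} holding every stage output
#'   plus a provenance record (parameters, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config

  expr <- run_stage("read_expression", {
    if (inherits(cf$expr, "expr_set")) cf$expr
    else read_expression(cf$expr, cf$metadata,
                         allow_duplicates = !is.null(cf$probe_map))
  })
  if (!is.null(cf$probe_map)) {
    pm <- if (is.character(cf$probe_map)) {
      utils::read.delim(cf$probe_map, stringsAsFactors = FALSE)
    } else cf$probe_map
    expr <- run_stage("collapse_probes", collapse_probes(expr, pm, cf$collapse_rule))
  }

  groups <- unique(expr$samples$group)
  healthier <- intersect(c(cf$control_group, cf$regenerated_group), groups)
  injured <- setdiff(groups, healthier)
  if (!length(injured)) stop("pipeline stage 'contrasts' failed: no injured groups")

  pertime <- run_stage("per_time_de", {
    out <- list()
    for (g in setdiff(groups, cf$control_group)) {
      res <- moderated_t_test(expr, de_contrast(paste0(g, "_vs_control"),
                                                g, cf$control_group))
      out[[g]] <- res
    }
    out
  })
  pertime_counts <- vapply(pertime, function(r) sum(r$fdr < cf$fdr_pertime),
                           integer(1L))

  de_main <- run_stage("injured_vs_healthier_de", {
    moderated_t_test(expr, de_contrast("injured_vs_healthier", injured, healthier))
  })
  selected <- run_stage("select_genes", select_genes(de_main, cf$fdr_select))
  if (length(selected) < 10L) {
    stop("pipeline stage 'select_genes' failed: fewer than 10 genes selected")
  }

  corr <- run_stage("correlation", correlation_matrix(expr, selected))
  net <- run_stage("soft_threshold", soft_threshold(corr, beta = cf$beta))
  thr <- run_stage("threshold_edges", {
    if (cf$filter_on == "correlation") {
      threshold_edges(net, r_threshold = cf$r_threshold)
    } else threshold_edges(net, tau = cf$tau)
  })
  stats_full <- run_stage("network_stats", network_stats(net))
  stats_thr <- run_stage("network_stats", network_stats(thr))

  tom <- run_stage("topological_overlap", topological_overlap(net))
  mods_h <- run_stage("modules_hierarchical", {
    do.call(detect_modules_hierarchical,
            c(list(tom = tom, expr = expr), cf$hier))
  })
  mods_c <- run_stage("modules_cohesive", {
    do.call(detect_modules_clusterone, c(list(net = thr), cf$cohesive))
  })
  jac <- if (length(mods_h$modules) && length(mods_c$modules)) {
    run_stage("jaccard", compare_modules_jaccard(mods_h, mods_c))
  } else NULL

  hubres <- run_stage("hub_test", {
    permutation_hub_test(thr, B = cf$hub_B, seed = cf$seed, null = cf$hub_null)
  })

  enr <- NULL
  if (!is.null(cf$annotations)) {
    ann <- if (is.character(cf$annotations)) read_gmt(cf$annotations) else cf$annotations
    enr <- run_stage("enrichment", {
      hypergeometric_enrichment(mods_h, ann, universe = selected,
                                alpha = cf$alpha_enrich)
    })
  }

  cons <- NULL
  mir <- NULL
  if (!is.null(cf$orthology)) {
    orth <- if (is.character(cf$orthology)) read_orthology(cf$orthology) else cf$orthology
    sp <- if (is.null(cf$species)) unique(orth$species) else cf$species
    cons <- run_stage("conservation", {
      stats::setNames(lapply(sp, function(s) conservation_chisq(hubres, orth, s)), sp)
    })
    if (!is.null(cf$mir_targets)) {
      mt <- if (is.character(cf$mir_targets)) read_mir_targets(cf$mir_targets) else cf$mir_targets
      mir <- run_stage("mir_mapping", {
        map_mir_targets(hubres, orth, mt, species = sp,
                        mir_whitelist = cf$mir_whitelist)
      })
    }
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("regenet")),
    seed = cf$seed,
    params = cf[c("control_group", "regenerated_group", "fdr_select",
                  "fdr_pertime", "beta", "tau", "filter_on", "r_threshold",
                  "hier", "cohesive", "hub_B", "hub_null", "alpha_enrich",
                  "collapse_rule")],
    n_genes_input = nrow(expr$exprs),
    n_samples = ncol(expr$exprs)
  )

  structure(list(
    expr = expr, de_pertime = pertime, pertime_counts = pertime_counts,
    de_main = de_main, selected = selected,
    network = net, network_thresholded = thr,
    network_stats = stats_full, network_stats_thresholded = stats_thr,
    modules_hierarchical = mods_h, modules_cohesive = mods_c, jaccard = jac,
    hubs = hubres, enrichment = enr, conservation = cons, mir = mir,
    provenance = prov
  ), class = "regen_bundle")
}

#' @export
print.regen_bundle <- function(x, ...) {
  cat("regen_bundle (regenet", x$provenance$package_version, ")\n")
  cat("  input:", x$provenance$n_genes_input, "genes x",
      x$provenance$n_samples, "samples\n")
  cat("  selected genes (", attr(x$selected, "contrast"), ", FDR < ",
      x$provenance$params$fdr_select, "): ", length(x$selected), "\n", sep = "")
  cat("  per-time DEG counts (FDR < ", x$provenance$params$fdr_pertime, "): ",
      paste(sprintf("%s=%d", names(x$pertime_counts), x$pertime_counts),
            collapse = ", "), "\n", sep = "")
  cat("  network:", x$network_stats_thresholded$n_nodes, "nodes,",
      x$network_stats_thresholded$n_edges, "edges at tau =",
      x$network_thresholded$tau, "\n")
  cat("  modules:", length(x$modules_hierarchical$modules), "hierarchical,",
      length(x$modules_cohesive$modules), "cohesive")
  if (!is.null(x$jaccard)) {
    b <- attr(x$jaccard, "best")
    cat(sprintf("; best overlap %s/%s J = %.3f", b$idA, b$idB, b$jaccard))
  }
  cat("\n  hubs:", sum(x$hubs$hub), "of", nrow(x$hubs), "network genes\n")
  if (!is.null(x$conservation)) {
    for (ct in x$conservation) {
      cat(sprintf("  conservation %s: chi2 = %s (p = %s), hub fraction %.2f\n",
                  ct$species, format(ct$statistic, digits = 4),
                  format(ct$p, digits = 3), ct$hub_fraction))
    }
  }
  if (!is.null(x$mir)) {
    sm <- attr(x$mir, "summary")
    cat("  miR interactions:", sm["validated"], "validated,",
        sm["predicted"], "predicted\n")
  }
  invisible(x)
}

#' @export
summary.regen_bundle <- function(object, ...) {
  x <- object
  out <- list(
    n_genes_input = x$provenance$n_genes_input,
    n_selected = length(x$selected),
    pertime_counts = x$pertime_counts,
    n_edges = x$network_stats_thresholded$n_edges,
    density = x$network_stats_thresholded$density,
    heterogeneity = x$network_stats_thresholded$heterogeneity,
    scale_free_r2 = x$network_stats$scale_free_r2,
    n_modules_hierarchical = length(x$modules_hierarchical$modules),
    n_modules_cohesive = length(x$modules_cohesive$modules),
    best_jaccard = if (!is.null(x$jaccard)) attr(x$jaccard, "best")$jaccard else NA_real_,
    n_hubs = sum(x$hubs$hub)
  )
  class(out) <- "summary.regen_bundle"
  out
}

#' @export
print.summary.regen_bundle <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Serialize a result bundle to files
#'
#' Writes, under \code{dir}: the selected gene list, the main and per-time
#' DE tables, the thresholded edge list, both module catalogs, the hub
#' table, enrichment / conservation / miR tables when present, and
#' \code{results.json} with the summary quantities and provenance. No
#' timestamps are written, so two runs with identical inputs, parameters and
#' seed produce byte-identical files.
#'
#' @param bundle A \code{regen_bundle}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "regen_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  writeLines(bundle$selected, file.path(dir, "selected_genes.txt"))
  paths <- c(paths, file.path(dir, "selected_genes.txt"))
  wt(bundle$de_main, "de_injured_vs_healthier.tsv")
  for (g in names(bundle$de_pertime)) {
    wt(bundle$de_pertime[[g]], paste0("de_", g, "_vs_control.tsv"))
  }
  write_network(bundle$network_thresholded, bundle$modules_hierarchical,
                bundle$hubs, file.path(dir, "network_edges.tsv"),
                format = "edgelist")
  paths <- c(paths, file.path(dir, "network_edges.tsv"))
  mod_df <- function(ms) {
    do.call(rbind, lapply(ms$modules, function(m) {
      data.frame(module = m$id, gene = m$genes, stringsAsFactors = FALSE)
    }))
  }
  if (length(bundle$modules_hierarchical$modules)) {
    wt(mod_df(bundle$modules_hierarchical), "modules_hierarchical.tsv")
  }
  if (length(bundle$modules_cohesive$modules)) {
    wt(mod_df(bundle$modules_cohesive), "modules_cohesive.tsv")
  }
  wt(bundle$hubs, "hubs.tsv")
  if (!is.null(bundle$enrichment)) wt(bundle$enrichment, "enrichment.tsv")
  if (!is.null(bundle$mir)) wt(bundle$mir, "mir_interactions.tsv")

  s <- summary(bundle)
  json <- list(summary = unclass(s), provenance = bundle$provenance)
  if (!is.null(bundle$conservation)) {
    json$conservation <- lapply(bundle$conservation, function(ct) {
      list(species = ct$species, chi2 = ct$statistic, p = ct$p,
           hub_fraction = ct$hub_fraction)
    })
  }
  jp <- file.path(dir, "results.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
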