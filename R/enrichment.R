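#' Hypergeometric functional enrichment of modules
#'
#' One-sided hypergeometric (upper-tail) test of every (module, term) pair
#' with a non-empty overlap, against a fixed gene universe. Annotations are
#' restricted to the universe before testing, p-values are BH-adjusted across
#' all tested pairs and significance is called at FDR < \code{alpha}.
#'
#' @param modules A \code{module_set} or named list of gene vectors; every
#'   module must be contained in the universe.
#' @param annotations An \code{annotation_table} (named list of gene
#'   vectors, e.g. from \code{\link{read_gmt}}).
#' @param universe Character vector of gene ids (typically the network's
#'   gene set).
#' @param alpha Significance level on the FDR.
#' @return Data frame of class \code{enrichment_result} with columns
#'   \code{module}, \code{term}, \code{overlap}, \code{module_size},
#'   \code{term_size}, \code{universe_size}, \code{p}, \code{fdr},
#'   \code{significant}.
#' @export
hypergeometric_enrichment <- function(modules, annotations, universe,
                                      alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  mods <- if (inherits(modules, "module_set")) module_genes(modules) else modules
  for (id in names(mods)) {
    if (!all(mods[[id]] %in% universe)) {
      stop("module ", id, " contains genes outside the universe")
    }
  }
  terms <- lapply(annotations, function(g) intersect(unique(g), universe))
  terms <- terms[lengths(terms) > 0]
  N <- length(universe)
  rows <- list()
  for (mid in names(mods)) {
    mg <- unique(mods[[mid]])
    for (tid in names(terms)) {
      tg <- terms[[tid]]
      ov <- length(intersect(mg, tg))
      if (ov < 1L) next
      p <- stats::phyper(ov - 1L, length(tg), N - length(tg), length(mg),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mid, term = tid, overlap = ov, module_size = length(mg),
        term_size = length(tg), universe_size = N, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(module = character(), term = character(),
                      overlap = integer(), module_size = integer(),
                      term_size = integer(), universe_size = integer(),
                      p = numeric(), fdr = numeric(), significant = logical())
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$p)
    out$significant <- out$fdr < alpha
  }
  structure(out, alpha = alpha, class = c("enrichment_result", "data.frame"))
}

#' Chi-square test of hub conservation in a mammalian species
#'
#' Builds the 2x2 contingency table (hub / non-hub) x (has ortholog / none)
#' for one species and applies the Pearson chi-square test on 1 df, by
#' default without continuity correction. Network genes absent from the
#' orthology table count as having no ortholog.
#'
#' @param hubres A \code{hub_result}.
#' @param orthology Data frame with columns \code{gene}, \code{species},
#'   \code{ortholog} (a \code{source} column is carried but ignored: one or
#'   more ortholog records of any source count as conserved).
#' @param species Species label to test.
#' @param correct Apply the Yates continuity correction? Default
#'   \code{FALSE}.
#' @return A list of class \code{conservation_test}: \code{species},
#'   \code{table}, \code{statistic}, \code{p}, \code{hub_fraction},
#'   \code{nonhub_fraction}, \code{note}.
#' @export
conservation_chisq <- function(hubres, orthology, species, correct = FALSE) {
  stopifnot(inherits(hubres, "hub_result"))
  orth <- orthology[orthology$species == species, , drop = FALSE]
  missing <- setdiff(hubres$gene, orthology$gene)
  if (length(missing)) {
    message(length(missing), " network gene(s) absent from the orthology table ",
            "counted as having no ortholog in ", species)
  }
  has_orth <- hubres$gene %in% orth$gene
  tab <- table(factor(ifelse(hubres$hub, "hub", "nonhub"),
                      levels = c("hub", "nonhub")),
               factor(ifelse(has_orth, "ortholog", "none"),
                      levels = c("ortholog", "none")))
  hub_frac <- if (sum(tab["hub", ]) > 0) tab["hub", "ortholog"] / sum(tab["hub", ]) else NA_real_
  nonhub_frac <- if (sum(tab["nonhub", ]) > 0) tab["nonhub", "ortholog"] / sum(tab["nonhub", ]) else NA_real_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(species = species, table = tab,
                          statistic = NA_real_, p = NA_real_,
                          hub_fraction = hub_frac,
                          nonhub_fraction = nonhub_frac,
                          note = "test undefined: a table margin is zero"),
                     class = "conservation_test"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(species = species, table = tab,
                 statistic = unname(ct$statistic), p = ct$p.value,
                 hub_fraction = hub_frac, nonhub_fraction = nonhub_frac,
                 note = NULL),
            class = "conservation_test")
}

#' @export
print.conservation_test <- function(x, ...) {
  cat(sprintf("conservation_test (%s): chi2 = %s, p = %s; hub ortholog fraction %.3f vs non-hub %.3f\n",
              x$species, format(x$statistic, digits = 4),
              format(x$p, digits = 3), x$hub_fraction, x$nonhub_fraction))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Map hub genes to miR-target interactions through orthology
#'
#' For each hub gene, its per-species orthologs are looked up and joined
#' against a local miR-target table (optionally restricted to a whitelist of
#' miR ids). Rows are de-duplicated to unique (miR, hub, species) triples and
#' counts are summarized per evidence class.
#'
#' @param hubres A \code{hub_result}.
#' @param orthology Data frame with columns \code{gene}, \code{species},
#'   \code{ortholog}.
#' @param mir_table Data frame with columns \code{mir}, \code{target}
#'   (ortholog id), \code{species}, \code{evidence} in
#'   \{validated, predicted\}.
#' @param species Species labels to consider.
#' @param mir_whitelist Optional miR ids to restrict to.
#' @return Data frame of class \code{mir_interaction_set} with columns
#'   \code{mir}, \code{hub}, \code{ortholog}, \code{species},
#'   \code{evidence}, and attribute \code{summary} (counts per evidence
#'   class).
#' @export
map_mir_targets <- function(hubres, orthology, mir_table,
                            species = unique(orthology$species),
                            mir_whitelist = NULL) {
  stopifnot(inherits(hubres, "hub_result"))
  unknown <- setdiff(species, unique(orthology$species))
  if (length(unknown)) stop("unknown species label(s): ", paste(unknown, collapse = ", "))
  hubs <- hubres$gene[hubres$hub]
  orth <- orthology[orthology$gene %in% hubs & orthology$species %in% species, ,
                    drop = FALSE]
  mt <- mir_table[mir_table$species %in% species, , drop = FALSE]
  if (!is.null(mir_whitelist)) mt <- mt[mt$mir %in% mir_whitelist, , drop = FALSE]
  out <- merge(
    data.frame(hub = orth$gene, ortholog = orth$ortholog,
               species = orth$species, stringsAsFactors = FALSE),
    data.frame(mir = mt$mir, ortholog = mt$target, species = mt$species,
               evidence = mt$evidence, stringsAsFactors = FALSE),
    by = c("ortholog", "species"))
  out <- out[, c("mir", "hub", "ortholog", "species", "evidence")]
  # a validated record outranks a predicted one for the same triple
  out <- out[order(match(out$evidence, c("validated", "predicted"))), , drop = FALSE]
  out <- out[!duplicated(out[, c("mir", "hub", "species")]), , drop = FALSE]
  out <- out[order(out$mir, out$hub, out$species), , drop = FALSE]
  rownames(out) <- NULL
  sm <- table(factor(out$evidence, levels = c("validated", "predicted")))
  structure(out, summary = c(validated = unname(sm["validated"]),
                             predicted = unname(sm["predicted"])),
            class = c("mir_interaction_set", "data.frame"))
}

#' @export
print.mir_interaction_set <- function(x, ...) {
  sm <- attr(x, "summary")
  cat("mir_interaction_set:", nrow(x), "unique (miR, hub, species) interactions;",
      sm["validated"], "validated,", sm["predicted"], "predicted\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
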