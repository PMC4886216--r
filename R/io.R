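#' Read a GMT annotation file
#'
#' Tab-separated rows: term, description, then one gene per field.
#'
#' @param path Path to the GMT file.
#' @return An \code{annotation_table}: named list of gene vectors with a
#'   \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) < 3L
  if (any(bad)) stop("GMT rows must have at least term, description and one gene")
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[[`, character(1L), 1L)
  desc <- stats::setNames(vapply(parts, `[[`, character(1L), 2L), names(terms))
  structure(terms, description = desc, class = "annotation_table")
}

#' Write an annotation table as GMT
#'
#' @param annotations An \code{annotation_table} or named list of gene
#'   vectors.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(annotations, path) {
  desc <- attr(annotations, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(annotations)),
                                             names(annotations))
  lines <- vapply(names(annotations), function(tm) {
    paste(c(tm, desc[[tm]], annotations[[tm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an orthology table (TSV: gene, species, ortholog, source)
#'
#' @param path Path to the TSV file.
#' @return Data frame with validated columns.
#' @export
read_orthology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "species", "ortholog")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("orthology table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df
}

#' Read a miR-target table (TSV: mir, target, species, evidence)
#'
#' @param path Path to the TSV file.
#' @return Data frame with validated columns; evidence must be
#'   \code{validated} or \code{predicted}.
#' @export
read_mir_targets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mir", "target", "species", "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("miR-target table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$evidence), c("validated", "predicted"))
  if (length(bad)) stop("evidence must be 'validated' or 'predicted'; found: ",
                        paste(bad, collapse = ", "))
  df
}

#' Export a network with module and hub annotations
#'
#' Writes the retained edges either as a TSV edge list (columns gene_a,
#' gene_b, weight, correlation_sign) or as GraphML with node attributes
#' \code{module_id}, \code{connectivity}, \code{hub} and \code{adjusted_p}.
#'
#' @param net A \code{weighted_network}.
#' @param modules Optional \code{module_set} supplying \code{module_id}
#'   (first containing module; "unassigned" otherwise).
#' @param hubres Optional \code{hub_result} supplying hub flags and adjusted
#'   p-values.
#' @param path Output path.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(net, modules = NULL, hubres = NULL, path,
                          format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.character(format) || !all(format %in% c("edgelist", "graphml"))) {
    stop("unknown format label: ", paste(setdiff(format, c("edgelist", "graphml")),
                                         collapse = ", "))
  }
  format <- match.arg(format)
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (format == "edgelist") {
    sgn <- if (!is.null(net$sign)) net$sign[idx] else rep(NA_integer_, nrow(idx))
    df <- data.frame(gene_a = net$nodes[idx[, 1L]],
                     gene_b = net$nodes[idx[, 2L]],
                     weight = w[idx],
                     correlation_sign = sgn,
                     stringsAsFactors = FALSE)
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph_from_network(net)
  module_id <- rep("unassigned", length(net$nodes))
  names(module_id) <- net$nodes
  if (!is.null(modules)) {
    for (m in rev(modules$modules)) module_id[intersect(m$genes, net$nodes)] <- m$id
  }
  igraph::V(g)$module_id <- unname(module_id[igraph::V(g)$name])
  igraph::V(g)$connectivity <- unname(rowSums(w)[igraph::V(g)$name])
  if (!is.null(hubres)) {
    hi <- match(igraph::V(g)$name, hubres$gene)
    igraph::V(g)$hub <- as.logical(hubres$hub[hi])
    igraph::V(g)$adjusted_p <- hubres$fdr[hi]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
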