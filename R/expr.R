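#' Expression set container
#'
#' Bundles a genes x samples matrix of log2 expression values with the sample
#' metadata (sample id, condition group, replicate). Columns of the matrix and
#' rows of the metadata must correspond one to one, in the same order.
#'
#' @param exprs Numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required).
#' @param samples Data frame with columns \code{sample}, \code{group},
#'   \code{replicate}.
#' @return An object of class \code{expr_set}: a list with elements
#'   \code{exprs} and \code{samples}.
#' @export
expression_set <- function(exprs, samples) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("expression values must be numeric")
  if (is.null(rownames(exprs))) stop("expression matrix must have gene rownames")
  if (is.null(colnames(exprs))) stop("expression matrix must have sample colnames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "group", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample <- as.character(samples$sample)
  samples$group <- as.character(samples$group)
  only_in_expr <- setdiff(colnames(exprs), samples$sample)
  only_in_meta <- setdiff(samples$sample, colnames(exprs))
  if (length(only_in_expr) || length(only_in_meta)) {
    stop(
      "sample mismatch between expression matrix and metadata;",
      if (length(only_in_expr)) paste0(" missing from metadata: ", paste(only_in_expr, collapse = ", ")),
      if (length(only_in_meta)) paste0(" missing from matrix: ", paste(only_in_meta, collapse = ", "))
    )
  }
  samples <- samples[match(colnames(exprs), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(exprs = exprs, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$exprs), "genes x", ncol(x$exprs), "samples\n")
  tab <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$exprs)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file is tab separated with gene ids in the first column and
#' one column per sample; the metadata file has columns \code{sample},
#' \code{group}, \code{replicate}. Windows (CRLF) line endings are accepted.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @param allow_duplicates Keep duplicated row ids (probe-level data awaiting
#'   \code{\link{collapse_probes}})? Default \code{FALSE}: duplicates error.
#' @return An \code{\link{expression_set}}.
#' @export
read_expression <- function(path, metadata_path, allow_duplicates = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(ids)) {
    if (!allow_duplicates) {
      stop("duplicate gene ids in ", path,
           "; supply a probe map and collapse_probes(), or set allow_duplicates = TRUE")
    }
    rownames(mat) <- NULL
    attr(mat, "row_ids") <- ids
  }
  rownames(mat) <- if (anyDuplicated(ids)) make.unique(ids) else ids
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  es <- expression_set(mat, meta)
  if (anyDuplicated(ids)) attr(es, "probe_ids") <- ids
  es
}

#' Write an expression set to TSV files
#'
#' @param expr An \code{expr_set}.
#' @param path Output path for the expression TSV (first column \code{gene}).
#' @param metadata_path Output path for the sample metadata TSV.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(expr, path, metadata_path) {
  df <- data.frame(gene = rownames(expr$exprs), expr$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' Probes absent from the map are dropped with a warning. Three collapse rules
#' are available: \code{"max-variance"} (default; keep the probe with the
#' largest sample variance), \code{"mean"} (average the probes) and
#' \code{"max-mean"} (keep the probe with the largest mean). Ties are broken
#' by probe id order, so the result is deterministic.
#'
#' @param expr An \code{expr_set} whose rows are probes.
#' @param probe_map Data frame with columns \code{probe} and \code{gene}.
#' @param rule Collapse rule, see above.
#' @return An \code{expr_set} with one row per gene.
#' @export
collapse_probes <- function(expr, probe_map,
                            rule = c("max-variance", "mean", "max-mean")) {
  rule <- match.arg(rule)
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map needs columns 'probe' and 'gene'")
  }
  probes <- rownames(expr$exprs)
  mapped <- probes %in% probe_map$probe
  if (!any(mapped)) stop("no probe in the expression matrix appears in probe_map")
  if (!all(mapped)) {
    warning(sum(!mapped), " probe(s) not in probe_map dropped: ",
            paste(utils::head(probes[!mapped], 5L), collapse = ", "),
            if (sum(!mapped) > 5L) ", ...")
  }
  x <- expr$exprs[mapped, , drop = FALSE]
  gene_of <- probe_map$gene[match(rownames(x), probe_map$probe)]
  ord <- order(gene_of, rownames(x))
  x <- x[ord, , drop = FALSE]
  gene_of <- gene_of[ord]
  pick <- function(rows) {
    sub <- x[rows, , drop = FALSE]
    switch(rule,
      "mean" = colMeans(sub),
      "max-variance" = sub[which.max(apply(sub, 1L, stats::var)), ],
      "max-mean" = sub[which.max(rowMeans(sub)), ]
    )
  }
  idx <- split(seq_len(nrow(x)), gene_of)
  out <- t(vapply(idx, pick, numeric(ncol(x))))
  colnames(out) <- colnames(x)
  expression_set(out, expr$samples)
}
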