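#' Define a two-group contrast
#'
#' @param name Label for the contrast (e.g. "injured_vs_healthier").
#' @param groupA,groupB Disjoint, non-empty sets of sample-group labels;
#'   the log2 fold change is mean(groupA) - mean(groupB).
#' @return An object of class \code{de_contrast}.
#' @export
de_contrast <- function(name, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both contrast sides must be non-empty")
  if (length(intersect(groupA, groupB))) stop("contrast sides must be disjoint")
  structure(list(name = name, groupA = groupA, groupB = groupB),
            class = "de_contrast")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; used by the moment estimator of the prior df.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  z <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(z)
    dif <- tri * (1 - tri / x) / psigamma(z, deriv = 2L)
    z <- z + dif
    if (-dif / z < 1e-8) break
  }
  z
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits a per-gene two-group comparison and shrinks the residual variances
#' towards a common prior by empirical Bayes. The prior degrees of freedom
#' \code{d0} and prior variance \code{s0^2} are estimated by closed-form
#' moment matching on \code{log(s^2)} (the scaled-F model of the gene-wise
#' sample variances): with \code{e_g = log(s_g^2) - digamma(d/2) + log(d/2)},
#' \code{d0} solves \code{trigamma(d0/2) = var(e) - trigamma(d/2)} and
#' \code{s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))}. The posterior
#' variance is \code{s2_post = (d0 s0^2 + d s^2) / (d0 + d)} and the
#' moderated t-statistic \code{logFC / sqrt(s2_post (1/nA + 1/nB))} is
#' referred to a t distribution on \code{d + d0} degrees of freedom.
#'
#' @param expr An \code{\link{expression_set}}.
#' @param contrast A \code{\link{de_contrast}}; at least 2 samples per side.
#' @param prior_df Optional forced prior df: \code{0} recovers the ordinary
#'   pooled-variance t-test, \code{Inf} fully shrinks every variance to
#'   \code{prior_var}.
#' @param prior_var Optional forced prior variance (required when
#'   \code{prior_df = Inf}; estimated from the data when \code{NULL}).
#' @return A \code{de_result}: a data frame with columns \code{gene},
#'   \code{logFC}, \code{s2}, \code{df}, \code{s2_post}, \code{t}, \code{p},
#'   \code{fdr}, with attributes \code{prior_df}, \code{prior_var},
#'   \code{contrast}, \code{nA}, \code{nB}.
#' @export
moderated_t_test <- function(expr, contrast, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(expr, "expr_set"), inherits(contrast, "de_contrast"))
  grp <- expr$samples$group
  unknown <- setdiff(c(contrast$groupA, contrast$groupB), unique(grp))
  if (length(unknown)) stop("contrast names unknown group(s): ", paste(unknown, collapse = ", "))
  iA <- which(grp %in% contrast$groupA)
  iB <- which(grp %in% contrast$groupB)
  nA <- length(iA); nB <- length(iB)
  if (nA < 2L || nB < 2L) stop("need at least 2 samples on each side of the contrast")
  xA <- expr$exprs[, iA, drop = FALSE]
  xB <- expr$exprs[, iB, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  ssA <- rowSums((xA - mA)^2)
  ssB <- rowSums((xB - mB)^2)
  d <- nA + nB - 2L
  s2 <- (ssA + ssB) / d
  logFC <- mA - mB

  pos <- s2 > 0
  if (is.null(prior_df)) {
    if (sum(pos) < 2L) stop("too few genes with positive residual variance to estimate the prior")
    if (!all(pos)) warning(sum(!pos), " gene(s) with zero residual variance excluded from prior estimation")
    e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
  } else {
    d0 <- prior_df
    s02 <- if (!is.null(prior_var)) prior_var else {
      if (is.infinite(d0) || d0 > 0) stop("prior_var must be supplied with a forced prior_df > 0")
      NA_real_
    }
  }
  if (!is.null(prior_var)) s02 <- prior_var

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    if (d0 > 0) (d0 * s02 + d * s2) / (d0 + d) else s2
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, logFC / se, sign(logFC) * Inf)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(gene = rownames(expr$exprs), logFC = logFC, s2 = s2,
                    df = d, s2_post = s2_post, t = tstat, p = p,
                    fdr = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, prior_df = d0, prior_var = s02, contrast = contrast$name,
            nA = nA, nB = nB, class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", attr(x, "contrast"), "-", nrow(x), "genes;",
      "prior df =", format(attr(x, "prior_df"), digits = 4),
      "prior var =", format(attr(x, "prior_var"), digits = 4), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Volcano plot of a moderated differential-expression result
#'
#' @param x A \code{de_result}.
#' @param fdr_threshold Highlighting threshold on the BH-adjusted p-value.
#' @param ... Passed to \code{plot}.
#' @export
plot.de_result <- function(x, fdr_threshold = 0.005, ...) {
  sig <- x$fdr < fdr_threshold
  plot(x$logFC, -log10(x$p), pch = 20, cex = 0.4,
       col = ifelse(sig, "firebrick", "grey50"),
       xlab = "log2 fold change", ylab = "-log10 p",
       main = attr(x, "contrast"), ...)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to 1 and monotone in rank.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("p-values must not contain NA")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Select genes by FDR threshold
#'
#' Returns the genes whose BH-adjusted p-value is strictly below the
#' threshold (the convention matched by "FDR < x" selection).
#'
#' @param res A \code{de_result}.
#' @param fdr_threshold Threshold in (0, 1).
#' @return Character vector of gene ids with attribute \code{contrast}.
#' @export
select_genes <- function(res, fdr_threshold = 0.005) {
  stopifnot(inherits(res, "de_result"))
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie strictly inside (0, 1)")
  }
  out <- res$gene[res$fdr < fdr_threshold]
  attr(out, "contrast") <- attr(res, "contrast")
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}
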