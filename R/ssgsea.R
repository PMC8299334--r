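#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum statistic for one sample: genes are ranked by
#' expression (average ranks for ties; higher expression, higher rank) and the
#' score is the sum over the descending-ordered gene list of the difference
#' between the weighted in-set empirical CDF (weights rank^alpha) and the
#' unweighted out-of-set empirical CDF. Depends on expression only through
#' ranks, so it is exactly invariant under any strictly increasing transform.
#'
#' @param sample_expression named numeric vector (the gene universe for this
#'   sample).
#' @param gene_set character vector of gene names; members absent from the
#'   universe are ignored.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return the enrichment score (a real number).
#' @export
ssgsea_score <- function(sample_expression, gene_set, alpha = 0.25) {
  if (is.null(names(sample_expression)))
    stop("sample_expression must be a named vector")
  genes <- names(sample_expression)
  inset <- genes %in% gene_set
  if (!any(inset)) stop("gene set has no member in the expressed universe")
  if (all(inset)) stop("gene set covers the whole universe; out-set is empty")
  r <- rank(sample_expression, ties.method = "average")
  # descending order; ties broken by gene name so the walk is deterministic
  # (tied genes carry identical rank weights either way)
  ord <- order(-sample_expression, genes)
  inset_ord <- inset[ord]
  w <- r[ord]^alpha
  w[!inset_ord] <- 0
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!inset_ord) / sum(!inset_ord)
  sum(cdf_in - cdf_out)
}

#' Immune and stromal enrichment scores per sample
#'
#' Applies \code{\link{ssgsea_score}} to an immune and a stromal gene set for
#' every sample of an expression matrix. No cross-sample normalization is
#' applied; scores are comparable across samples through the shared universe.
#'
#' @param x an \code{expr_matrix}.
#' @param immune_set,stromal_set character vectors of gene names.
#' @param alpha rank-weighting exponent.
#' @return data.frame with columns \code{sample_id}, \code{immune_score},
#'   \code{stromal_score}.
#' @export
estimate_scores <- function(x, immune_set, stromal_set, alpha = 0.25) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- unclass(x)
  score_one <- function(j, set)
    ssgsea_score(stats::setNames(vals[, j], rownames(vals)), set, alpha)
  data.frame(
    sample_id = colnames(x),
    immune_score = vapply(seq_len(ncol(x)), score_one, 0, set = immune_set),
    stromal_score = vapply(seq_len(ncol(x)), score_one, 0, set = stromal_set),
    stringsAsFactors = FALSE)
}
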