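#' First-principal-component projection of a gene signature
#'
#' Restricts expression to the signature genes, applies log2(x+1), centers
#' and unit-scales each gene, and projects every sample onto the first
#' principal component of the samples-by-genes matrix. The component's sign
#' is fixed deterministically: it is flipped if the sum of its loadings is
#' negative (and, if the sum is exactly zero, if the first nonzero loading is
#' negative), so repeated runs and different linear-algebra backends agree
#' bit for bit. Projections are centered (mean zero) by construction.
#'
#' @param x an \code{expr_matrix} (>= 3 samples).
#' @param genes signature gene list (>= 2 usable genes after dropping those
#'   absent or with zero variance).
#' @return named numeric vector of per-sample PC1 projections.
#' @export
pc1_scores <- function(x, genes) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x) < 3) stop("need at least 3 samples")
  genes <- intersect(genes, rownames(x))
  M <- t(log2(unclass(x)[genes, , drop = FALSE] + 1))
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropped ", sum(sds == 0), " zero-variance gene(s)")
    M <- M[, sds > 0, drop = FALSE]
  }
  if (ncol(M) < 2) stop("fewer than 2 usable signature genes")
  pr <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  load <- pr$rotation[, 1]
  s <- sum(load)
  flip <- if (s != 0) s < 0 else load[which(load != 0)[1]] < 0
  sign <- if (flip) -1 else 1
  stats::setNames(sign * pr$x[, 1], rownames(M))
}

#' Per-sample immune-cell-infiltration score
#'
#' The headline statistic: \code{ici_score = PC1(signature A) -
#' PC1(signature B)} per sample, the difference of the two signatures'
#' first-principal-component projections. Exactly antisymmetric under
#' swapping A and B, and identically zero when the two signatures coincide.
#'
#' @param x an \code{expr_matrix}.
#' @param pair a \code{gene_signature_pair}.
#' @return data.frame with columns \code{sample_id}, \code{pc1_a},
#'   \code{pc1_b}, \code{ici_score}.
#' @export
ici_score <- function(x, pair) {
  stopifnot(inherits(pair, "gene_signature_pair"))
  a <- pc1_scores(x, pair$signature_a)
  b <- pc1_scores(x, pair$signature_b)
  data.frame(sample_id = colnames(x),
             pc1_a = as.numeric(a[colnames(x)]),
             pc1_b = as.numeric(b[colnames(x)]),
             ici_score = as.numeric(a[colnames(x)] - b[colnames(x)]),
             stringsAsFactors = FALSE)
}

#' Dichotomize scores at a cutoff
#'
#' Scores strictly above the cutoff are "high", the rest "low" (the boundary
#' goes to "low"). A warning is raised if either group is empty.
#'
#' @param scores numeric vector of finite scores.
#' @param cutoff the threshold, typically from \code{\link{youden_cutoff}}.
#' @return factor with levels \code{low}, \code{high}.
#' @export
dichotomize <- function(scores, cutoff) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  g <- factor(ifelse(scores > cutoff, "high", "low"),
              levels = c("low", "high"))
  if (any(table(g) == 0))
    warning("dichotomization produced an empty group (cutoff = ", cutoff, ")")
  g
}
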