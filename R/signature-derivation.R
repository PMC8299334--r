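#' Differential genes between clusters (all pairwise contrasts)
#'
#' Per gene and cluster pair: two-sided Wilcoxon rank-sum p-value and a
#' log2 fold-change computed as \code{log2(mean_a + 1) - log2(mean_b + 1)}.
#' P-values are Benjamini-Hochberg adjusted within each contrast, and a gene
#' is selected in a contrast when adjusted p < 0.05 and |log2 fold-change| >
#' 1 (the fold-change cutoff read on the log2 scale, where it excludes
#' genes changing less than two-fold).
#'
#' @param x an \code{expr_matrix}.
#' @param labels per-sample cluster labels, either named by sample or aligned
#'   with \code{colnames(x)}.
#' @param p_cut adjusted-p threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{log2fc}, \code{p}, \code{p_adj}, \code{selected}.
#' @export
differential_genes <- function(x, labels, p_cut = 0.05, lfc_cut = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  if (length(labels) != ncol(x)) stop("labels must cover every sample")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes < 3))
    stop("cluster(s) with fewer than 3 samples: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  vals <- unclass(x)
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    ia <- which(labels == pr[1]); ib <- which(labels == pr[2])
    p <- apply(vals, 1, function(v)
      suppressWarnings(stats::wilcox.test(v[ia], v[ib], exact = FALSE,
                                          correct = TRUE)$p.value))
    p[is.na(p)] <- 1  # constant gene in both groups
    lfc <- log2(rowMeans(vals[, ia, drop = FALSE]) + 1) -
      log2(rowMeans(vals[, ib, drop = FALSE]) + 1)
    data.frame(gene = rownames(vals),
               contrast = paste(pr, collapse = "_vs_"),
               log2fc = lfc, p = p,
               p_adj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$selected <- out$p_adj < p_cut & abs(out$log2fc) > lfc_cut
  out
}

#' Union of genes selected in at least one contrast
#' @param deg a DEG table from \code{\link{differential_genes}}
#' @return character vector of gene names
#' @export
deg_union <- function(deg) sort(unique(deg$gene[deg$selected]))

#' Gene-cluster assignment of samples from their DEG expression
#'
#' Consensus-clusters the samples (k = 2 by default) on the z-scored
#' log2(x+1) expression of the DEG union, yielding the two gene clusters.
#'
#' @param x an \code{expr_matrix}.
#' @param genes DEG union (length >= 2 after zero-variance removal).
#' @param k number of gene clusters (default 2).
#' @param ... passed to \code{\link{consensus_cluster}}.
#' @return named integer vector of per-sample labels in 1..k.
#' @export
gene_clusters <- function(x, genes, k = 2, ...) {
  genes <- intersect(genes, rownames(x))
  if (length(genes) < 2) stop("need at least 2 DEGs present in the matrix")
  M <- t(log2(unclass(x)[genes, , drop = FALSE] + 1))
  sds <- apply(M, 2, stats::sd)
  if (all(sds == 0)) stop("DEG expression is constant across samples")
  res <- consensus_cluster(M, k_range = k, scale_features = TRUE, ...)
  res$labels[[paste0("k", k)]]
}

#' Split DEGs into signatures A and B by correlation with gene-cluster
#' membership
#'
#' With an indicator equal to 1 for samples in the gene cluster named
#' \code{positive_cluster} and 0 otherwise, each gene's Pearson correlation
#' with the indicator decides its side: positive, signature A; negative,
#' signature B; zero or undefined (constant gene), dropped with a warning.
#' Swapping which cluster is called positive swaps A and B exactly.
#'
#' @param x an \code{expr_matrix}.
#' @param genes DEG union.
#' @param gene_cluster_labels named per-sample labels from
#'   \code{\link{gene_clusters}}.
#' @param positive_cluster label treated as gene cluster A (default 1).
#' @return list of class \code{gene_signature_pair}: \code{signature_a},
#'   \code{signature_b}.
#' @export
split_signatures <- function(x, genes, gene_cluster_labels,
                             positive_cluster = 1) {
  genes <- intersect(genes, rownames(x))
  lab <- gene_cluster_labels[colnames(x)]
  if (any(is.na(lab))) stop("gene_cluster_labels must cover every sample")
  indicator <- as.numeric(lab == positive_cluster)
  if (all(indicator == 0) || all(indicator == 1))
    stop("both gene clusters must be non-empty")
  M <- log2(unclass(x)[genes, , drop = FALSE] + 1)
  r <- suppressWarnings(apply(M, 1, stats::cor, y = indicator))
  dropped <- genes[is.na(r) | r == 0]
  if (length(dropped))
    warning("dropped ", length(dropped),
            " gene(s) with zero variance or zero correlation")
  pair <- structure(list(signature_a = genes[!is.na(r) & r > 0],
                         signature_b = genes[!is.na(r) & r < 0]),
                    class = "gene_signature_pair")
  pair
}

#' @export
print.gene_signature_pair <- function(x, ...) {
  cat(sprintf("gene_signature_pair: A = %d genes, B = %d genes\n",
              length(x$signature_a), length(x$signature_b)))
  invisible(x)
}

#' Boruta all-relevant feature selection
#'
#' Each iteration pairs every feature with a "shadow" copy whose values are
#' independently permuted, grows a random forest on the augmented matrix, and
#' credits a feature with a hit when its impurity importance exceeds the
#' maximum shadow importance. After \code{n_iter} iterations a two-sided
#' binomial test (level 0.01) against the 0.5 hit rate classifies features as
#' confirmed, rejected, or tentative; tentative features are resolved by
#' comparing their median importance to the median of the per-iteration
#' shadow maxima.
#'
#' @param features samples x features numeric matrix with column names.
#' @param target per-sample class labels (two or more classes).
#' @param n_iter iterations; at least 8 so the binomial test can reach
#'   significance at 0.01.
#' @param num_trees trees per forest (default 100).
#' @param seed integer seed.
#' @return character vector of confirmed feature names (attribute
#'   \code{"decision"}: the full confirmed/rejected/tentative classification).
#' @export
boruta_select <- function(features, target, n_iter = 100, num_trees = 100,
                          seed = 1) {
  features <- as.matrix(features)
  if (ncol(features) < 5) stop("need at least 5 features")
  if (is.null(colnames(features))) stop("features must have column names")
  target <- as.factor(target)
  if (nlevels(droplevels(target)) < 2)
    stop("target must contain at least two classes")
  if (n_iter < 8)
    stop("n_iter must be >= 8 for the binomial test to reach level 0.01")
  p <- ncol(features)
  hits <- integer(p)
  imp_hist <- matrix(NA_real_, n_iter, p)
  shadow_max <- numeric(n_iter)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    shadow <- apply(features, 2, sample)
    colnames(shadow) <- paste0(".shadow.", colnames(features))
    df <- data.frame(cbind(features, shadow), check.names = FALSE)
    df$.target <- target
    fit <- ranger::ranger(dependent.variable.name = ".target", data = df,
                          num.trees = num_trees, importance = "impurity",
                          num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$variable.importance
    real <- imp[colnames(features)]
    smax <- max(imp[colnames(shadow)])
    hits <- hits + (real > smax)
    imp_hist[it, ] <- real
    shadow_max[it] <- smax
  }
  p_hi <- stats::pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, n_iter, 0.5)
  decision <- rep("tentative", p)
  decision[p_hi < 0.005] <- "confirmed"
  decision[p_lo < 0.005] <- "rejected"
  tent <- decision == "tentative"
  if (any(tent)) {
    med_imp <- apply(imp_hist[, tent, drop = FALSE], 2, stats::median)
    decision[tent][med_imp > stats::median(shadow_max)] <- "confirmed"
    decision[tent][decision[tent] == "tentative"] <- "rejected"
  }
  confirmed <- colnames(features)[decision == "confirmed"]
  attr(confirmed, "decision") <- stats::setNames(decision, colnames(features))
  confirmed
}

#' Boruta reduction of a signature pair
#'
#' Runs \code{\link{boruta_select}} separately on each signature's log2(x+1)
#' expression against the gene-cluster labels and keeps the confirmed genes.
#' If nothing in a signature is confirmed the signature is left unreduced
#' with a warning (the pair must stay non-empty).
#'
#' @param x an \code{expr_matrix}.
#' @param pair a \code{gene_signature_pair}.
#' @param gene_cluster_labels per-sample gene-cluster labels.
#' @param jointly run one Boruta on A and B together instead of per signature.
#' @param ... passed to \code{\link{boruta_select}}.
#' @return reduced \code{gene_signature_pair}.
#' @export
reduce_signatures <- function(x, pair, gene_cluster_labels, jointly = FALSE,
                              ...) {
  stopifnot(inherits(pair, "gene_signature_pair"))
  lab <- gene_cluster_labels[colnames(x)]
  reduce_one <- function(genes) {
    genes <- intersect(genes, rownames(x))
    if (length(genes) < 5) {
      warning("signature smaller than 5 genes; left unreduced")
      return(genes)
    }
    M <- t(log2(unclass(x)[genes, , drop = FALSE] + 1))
    keep <- boruta_select(M, lab, ...)
    if (!length(keep)) {
      warning("Boruta confirmed no gene; signature left unreduced")
      genes
    } else as.character(keep)
  }
  if (jointly) {
    both <- reduce_one(c(pair$signature_a, pair$signature_b))
    out <- list(signature_a = intersect(pair$signature_a, both),
                signature_b = intersect(pair$signature_b, both))
    if (!length(out$signature_a) || !length(out$signature_b)) {
      warning("joint Boruta emptied a signature; pair left unreduced")
      out <- pair[c("signature_a", "signature_b")]
    }
  } else {
    out <- list(signature_a = reduce_one(pair$signature_a),
                signature_b = reduce_one(pair$signature_b))
  }
  structure(out, class = "gene_signature_pair")
}
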