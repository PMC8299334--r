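#' End-to-end immune-infiltration scoring pipeline
#'
#' Chains every stage on one cohort: reference-based deconvolution (optional
#' permutation filter), consensus clustering of the immune-fraction
#' landscape into \code{k_ici} infiltration clusters, pairwise differential
#' expression between the clusters, consensus gene-clustering of the samples
#' on the DEG union, correlation-based split into signatures A and B, Boruta
#' reduction, the per-sample score PC1(A) - PC1(B), Youden-cutoff
#' dichotomization against the death indicator, log-rank survival
#' comparison of the score groups, and — when mutation and TRG data are
#' supplied — mutational-burden analyses and chemotherapy-response
#' comparison.
#'
#' @param expression an \code{expr_matrix} (TPM scale).
#' @param signature marker genes x cell types reference matrix.
#' @param clinical validated clinical table covering the samples.
#' @param mutations optional mutation table for TMB analyses.
#' @param solver deconvolution solver (\code{"nnls"} default).
#' @param n_perm permutations for the effective-sample filter; 0 (default)
#'   skips filtering.
#' @param alpha permutation-filter threshold.
#' @param k_ici number of infiltration clusters (default 3).
#' @param k_gene number of gene clusters (default 2).
#' @param n_resample consensus subsampling rounds (default 100).
#' @param boruta_iter Boruta iterations (default 30).
#' @param boruta_trees trees per Boruta forest (default 50).
#' @param exome_mb TMB denominator in megabases.
#' @param seed integer seed controlling every stochastic stage.
#' @return list of class \code{ici_pipeline_result}: \code{fractions},
#'   \code{ici_cluster}, \code{cluster_survival}, \code{deg}, \code{deg_union},
#'   \code{gene_cluster}, \code{signatures}, \code{scores} (with score
#'   group), \code{cutoff}, \code{score_survival}, \code{tmb},
#'   \code{tmb_results}, \code{response}, \code{seed}.
#' @export
run_ici_pipeline <- function(expression, signature, clinical,
                             mutations = NULL,
                             solver = "nnls", n_perm = 0, alpha = 0.05,
                             k_ici = 3, k_gene = 2, n_resample = 100,
                             boruta_iter = 30, boruta_trees = 50,
                             exome_mb = 38, seed = 1) {
  stopifnot(inherits(expression, "expr_matrix"))
  clinical <- validate_clinical(clinical)
  if (!all(colnames(expression) %in% clinical$sample_id))
    stop("clinical table must cover every expression sample")

  fractions <- deconvolve_cohort(expression, signature, solver = solver,
                                 n_perm = n_perm, seed = seed)
  effective <- if (n_perm > 0) filter_effective(fractions, alpha) else fractions
  samples <- rownames(effective$fractions)
  expr <- expression[, samples]
  cl <- clinical[match(samples, clinical$sample_id), ]

  cc <- consensus_cluster(effective$fractions, k_range = k_ici,
                          n_resample = n_resample, seed = seed)
  ici_cluster <- cc$labels[[paste0("k", k_ici)]]
  cluster_survival <- logrank_test(cl$os_time, cl$os_event,
                                   paste0("ICI-", LETTERS[ici_cluster]))

  deg <- differential_genes(expr, ici_cluster)
  degs <- deg_union(deg)
  if (length(degs) < 2)
    stop("fewer than 2 differential genes between infiltration clusters")

  gc_labels <- gene_clusters(expr, degs, k = k_gene,
                             n_resample = n_resample, seed = seed + 1)
  # orient the pair deterministically: gene cluster A (whose upregulated
  # genes become signature A, pushing the score up) is the cluster with the
  # worst observed/expected mortality, so a high score means poor prognosis
  gc_surv <- logrank_test(cl$os_time, cl$os_event, gc_labels)
  oe <- gc_surv$obs / pmax(gc_surv$exp, 1e-12)
  positive <- sort(unique(gc_labels))[which.max(oe)]
  pair <- split_signatures(expr, degs, gc_labels, positive_cluster = positive)
  pair <- reduce_signatures(expr, pair, gc_labels, n_iter = boruta_iter,
                            num_trees = boruta_trees, seed = seed + 2)

  scores <- ici_score(expr, pair)
  yc <- youden_cutoff(scores$ici_score, cl$os_event)
  scores$group <- dichotomize(scores$ici_score, yc$cutoff)
  score_survival <- logrank_test(cl$os_time, cl$os_event, scores$group)

  tmb <- NULL; tmb_results <- NULL
  if (!is.null(mutations)) {
    tmb <- tmb_per_sample(mutations, samples, exome_mb = exome_mb)
    tmb_results <- tmb_analyses(scores, tmb, cl)
  }
  response <- NULL
  if (any(!is.na(cl$trg))) {
    keep <- !is.na(cl$trg)
    resp <- trg_response(cl$trg[keep])
    if (nlevels(droplevels(resp)) == 2)
      response <- response_compare(scores$ici_score[keep], resp)
  }

  structure(list(
    fractions = fractions, effective = effective, ici_cluster = ici_cluster,
    cluster_survival = cluster_survival, deg = deg, deg_union = degs,
    gene_cluster = gc_labels, signatures = pair, scores = scores,
    cutoff = yc, score_survival = score_survival,
    tmb = tmb, tmb_results = tmb_results, response = response,
    seed = seed), class = "ici_pipeline_result")
}

#' @export
print.ici_pipeline_result <- function(x, ...) {
  cat("ICI scoring pipeline result\n")
  cat(sprintf("  samples analyzed: %d (of %d deconvolved)\n",
              nrow(x$effective$fractions), nrow(x$fractions$fractions)))
  cat(sprintf("  infiltration clusters: %d | DEGs: %d | signature A/B: %d/%d\n",
              length(unique(x$ici_cluster)), length(x$deg_union),
              length(x$signatures$signature_a),
              length(x$signatures$signature_b)))
  cat(sprintf("  score cutoff (Youden): %.4f (J = %.3f)\n",
              x$cutoff$cutoff, x$cutoff$J))
  cat(sprintf("  score-group log-rank p: %.4g\n", x$score_survival$p))
  if (!is.null(x$tmb_results))
    cat(sprintf("  Spearman(score, TMB): %.3f | TMB Wilcoxon p: %.4g\n",
                x$tmb_results$spearman$rho, x$tmb_results$wilcoxon$p))
  if (!is.null(x$response))
    cat(sprintf("  response: median score major %.3f vs minor %.3f (p=%.4g)\n",
                x$response$median_major, x$response$median_minor,
                x$response$p))
  invisible(x)
}
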