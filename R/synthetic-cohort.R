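#' The 22-cell-type immune panel used by the synthetic generator
#' @format character vector of 22 cell-type names
#' @export
immune_panel_22 <- c(
  "B.cells.naive", "B.cells.memory", "Plasma.cells", "T.cells.CD8",
  "T.cells.CD4.naive", "T.cells.CD4.memory.resting",
  "T.cells.CD4.memory.activated", "T.cells.follicular.helper",
  "T.cells.regulatory.Tregs", "T.cells.gamma.delta", "NK.cells.resting",
  "NK.cells.activated", "Monocytes", "Macrophages.M0", "Macrophages.M1",
  "Macrophages.M2", "Dendritic.cells.resting", "Dendritic.cells.activated",
  "Mast.cells.resting", "Mast.cells.activated", "Eosinophils", "Neutrophils"
)

#' Simulation configuration for synthetic tumor cohorts
#'
#' Defines the generative model: per-sample latent immunophenotype cluster,
#' Dirichlet cell-type mixtures per cluster, marker-gene reference signature,
#' cluster-linked differential genes, exponential survival with per-cluster
#' hazard ratios, mutation loads rank-correlated with the latent score, and
#' tumor-regression-grade response labels.
#'
#' @param n_samples number of samples.
#' @param n_genes total genes (markers plus background); must be at least
#'   \code{n_celltypes * n_marker_genes_per_celltype + n_clusters *
#'   n_de_genes_per_cluster}.
#' @param n_celltypes number of immune cell types (default 22, the standard
#'   deconvolution panel).
#' @param n_clusters number of latent immunophenotype clusters (default 3).
#' @param dirichlet_concentration list of per-cluster positive concentration
#'   vectors (length \code{n_celltypes}); the default enriches a disjoint
#'   block of five cell types per cluster (weight 4 vs 1) at total
#'   concentration 150, giving well-separated but overlapping mixtures.
#' @param noise_sd additive Gaussian noise sd on the natural expression scale
#'   (truncated at zero) before TPM rescaling.
#' @param n_marker_genes_per_celltype markers per cell type in the reference.
#' @param n_de_genes_per_cluster background genes upregulated in each cluster.
#' @param de_log2fc planted log2 fold-change of cluster genes.
#' @param hazard_ratios per-cluster hazard multipliers; default spaces the
#'   extreme clusters a factor 2 apart, highest hazard for the
#'   highest-latent-score cluster.
#' @param baseline_hazard events per month for the reference cluster.
#' @param censor_rate probability a sample is censored (uniformly before its
#'   event time).
#' @param latent_sd within-cluster standard deviation of the continuous
#'   latent immunophenotype score around its cluster mean (cluster means are
#'   equally spaced on [-1, 1]).
#' @param tmb_score_correlation target Spearman correlation between mutation
#'   count and the latent score (negative: immune-hot, high-score samples
#'   carry fewer mutations).
#' @param mean_mutations mean per-sample mutation count.
#' @param seed integer seed; every draw derives from it via fixed
#'   per-component substreams.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 300,
                       n_genes = 500,
                       n_celltypes = 22,
                       n_clusters = 3,
                       dirichlet_concentration = NULL,
                       noise_sd = 5,
                       n_marker_genes_per_celltype = 5,
                       n_de_genes_per_cluster = 50,
                       de_log2fc = 3,
                       latent_sd = 0.4,
                       hazard_ratios = NULL,
                       baseline_hazard = 0.02,
                       censor_rate = 0.3,
                       tmb_score_correlation = -0.5,
                       mean_mutations = 120,
                       seed = 1) {
  stopifnot(n_samples >= 1, n_genes >= 1, n_celltypes >= 2, n_clusters >= 2,
            noise_sd >= 0, de_log2fc > 0, latent_sd >= 0, baseline_hazard > 0,
            censor_rate >= 0, censor_rate <= 1,
            tmb_score_correlation >= -1, tmb_score_correlation <= 1)
  if (is.null(hazard_ratios))
    hazard_ratios <- 2^(n_clusters - seq_len(n_clusters))
  if (length(hazard_ratios) != n_clusters || any(hazard_ratios <= 0))
    stop("hazard_ratios must be ", n_clusters, " positive values")
  if (is.null(dirichlet_concentration)) {
    block <- max(1L, n_celltypes %/% n_clusters)
    dirichlet_concentration <- lapply(seq_len(n_clusters), function(c) {
      w <- rep(1, n_celltypes)
      idx <- ((c - 1L) * block + 1L):min(c * block, n_celltypes)
      w[idx] <- 4
      150 * w / sum(w)
    })
  }
  ok <- vapply(dirichlet_concentration,
               function(a) length(a) == n_celltypes && all(a > 0), TRUE)
  if (length(dirichlet_concentration) != n_clusters || !all(ok))
    stop("dirichlet_concentration must be ", n_clusters,
         " strictly positive vectors of length ", n_celltypes)
  n_marker <- n_celltypes * n_marker_genes_per_celltype
  if (n_genes < n_marker + n_clusters * n_de_genes_per_cluster)
    stop("n_genes too small: need >= ",
         n_marker + n_clusters * n_de_genes_per_cluster)
  structure(list(
    n_samples = n_samples, n_genes = n_genes, n_celltypes = n_celltypes,
    n_clusters = n_clusters, dirichlet_concentration = dirichlet_concentration,
    noise_sd = noise_sd,
    n_marker_genes_per_celltype = n_marker_genes_per_celltype,
    n_de_genes_per_cluster = n_de_genes_per_cluster, de_log2fc = de_log2fc,
    latent_sd = latent_sd,
    hazard_ratios = hazard_ratios, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, tmb_score_correlation = tmb_score_correlation,
    mean_mutations = mean_mutations, seed = as.integer(seed)
  ), class = "sim_config")
}

# fixed substream offsets: each generative component reseeds independently so
# one component's draws never perturb another's
.sim_stream <- function(config, offset) {
  set.seed((config$seed * 101L + offset) %% .Machine$integer.max)
}

.celltype_names <- function(config) {
  if (config$n_celltypes == 22) immune_panel_22
  else paste0("celltype", seq_len(config$n_celltypes))
}

#' Generate a marker-gene reference signature matrix
#'
#' Each cell type receives \code{n_marker_genes_per_celltype} marker genes
#' drawn log-normal around a high location in the owning cell type and a low
#' location (25x lower) elsewhere, the classical structure of deconvolution
#' reference panels.
#'
#' @param config a \code{\link{sim_config}}.
#' @return non-negative matrix, marker genes x cell types.
#' @export
generate_signature_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_stream(config, 1L)
  types <- .celltype_names(config)
  nm <- config$n_marker_genes_per_celltype
  genes <- as.vector(vapply(types, function(t) paste0("MK.", t, ".", seq_len(nm)),
                            character(nm)))
  S <- matrix(exp(stats::rnorm(length(genes) * length(types),
                               mean = log(20), sd = 0.25)),
              nrow = length(genes), ncol = length(types),
              dimnames = list(genes, types))
  for (j in seq_along(types)) {
    idx <- ((j - 1L) * nm + 1L):(j * nm)
    S[idx, j] <- exp(stats::rnorm(nm, mean = log(500), sd = 0.25))
  }
  S
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cohort with full ground truth
#'
#' Draws, per sample: a latent cluster (uniform), cell-type fractions
#' (cluster-specific Dirichlet), a continuous latent immunophenotype score
#' (cluster mean plus Gaussian jitter), bulk expression (signature times
#' fractions for marker genes, a shared baseline for background genes,
#' cluster genes multiplied by \code{2^de_log2fc}, truncated Gaussian noise,
#' TPM rescaling), exponential survival with cluster hazard ratios,
#' mutation counts coupled to the latent score through a Gaussian copula at
#' the configured Spearman correlation, and a Mandard TRG drawn with
#' major-response probability decreasing in the latent score.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{synthetic_cohort} with elements
#'   \code{expression} (\code{expr_matrix}, TPM), \code{true_fractions}
#'   (samples x cell types), \code{true_cluster}, \code{latent},
#'   \code{signature_matrix}, \code{clinical}, \code{mutations},
#'   \code{planted_de_genes} (list per cluster), \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  K <- config$n_clusters
  samples <- sprintf("S%04d", seq_len(n))
  types <- .celltype_names(config)

  S <- generate_signature_matrix(config)
  n_marker <- nrow(S)
  n_bg <- config$n_genes - n_marker
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))

  # cluster assignment and continuous latent score (cluster means descend
  # from +1 to -1; cluster 1 is the immune-hot, high-score, high-hazard one)
  .sim_stream(config, 2L)
  cluster <- sample.int(K, n, replace = TRUE)
  mu <- seq(1, -1, length.out = K)
  latent <- mu[cluster] + stats::rnorm(n, sd = config$latent_sd)

  .sim_stream(config, 3L)
  F <- matrix(NA_real_, n, config$n_celltypes,
              dimnames = list(samples, types))
  for (c in seq_len(K)) {
    idx <- which(cluster == c)
    if (length(idx))
      F[idx, ] <- .rdirichlet(length(idx), config$dirichlet_concentration[[c]])
  }

  # background baseline shared by all samples; planted cluster genes sit in
  # the background block
  .sim_stream(config, 4L)
  baseline <- exp(stats::rnorm(n_bg, mean = log(50), sd = 0.7))
  nde <- config$n_de_genes_per_cluster
  planted <- lapply(seq_len(K), function(c)
    bg_genes[((c - 1L) * nde + 1L):(c * nde)])
  names(planted) <- paste0("cluster", seq_len(K))

  E_marker <- S %*% t(F)
  E_bg <- matrix(baseline, n_bg, n, dimnames = list(bg_genes, samples))
  # cluster c's block is maximally up at its own cluster's latent mean and
  # responds gradually along the continuous latent axis through a linear
  # kernel of width 3/4 of the latent range, so the differential structure
  # carries the score-driving latent the way real immune-expression programs
  # do while every block still separates its own cluster from its neighbors
  # by more than a two-fold change; between a block's own cluster center and
  # the farthest center the planted log2 fold-change is exactly de_log2fc
  width <- 0.75 * diff(range(mu))
  for (c in seq_len(K)) {
    affinity <- pmax(0, 1 - abs(mu[c] - latent) / width)
    shift <- 2^(config$de_log2fc * affinity)
    E_bg[planted[[c]], ] <- E_bg[planted[[c]], , drop = FALSE] *
      rep(shift, each = nde)
  }
  E <- rbind(E_marker, E_bg)

  .sim_stream(config, 5L)
  if (config$noise_sd > 0)
    E <- pmax(E + matrix(stats::rnorm(length(E), sd = config$noise_sd),
                         nrow(E), ncol(E)), 0)
  E <- sweep(E, 2, colSums(E), "/") * 1e6
  expression <- expr_matrix(E, unit = "TPM")

  # survival: exponential event times with independent exponential censoring
  # whose rate is calibrated so each subject is censored with probability
  # censor_rate
  .sim_stream(config, 6L)
  rate <- config$baseline_hazard * config$hazard_ratios[cluster]
  t_event <- stats::rexp(n, rate = rate)
  if (config$censor_rate >= 1) {
    os_time <- t_event; os_event <- rep(0, n)
  } else if (config$censor_rate <= 0) {
    os_time <- t_event; os_event <- rep(1, n)
  } else {
    c_rate <- rate * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.numeric(t_event <= t_cens)
  }

  .sim_stream(config, 7L)
  age <- pmin(pmax(stats::rnorm(n, 62, 10), 25), 90)
  sex <- ifelse(stats::runif(n) < 0.65, "male", "female")
  stage <- ifelse(stats::runif(n) < 0.5, "early", "advanced")

  # mutation count coupled to the latent score: Gaussian copula on the
  # latent's normal scores, Pearson parameter back-transformed from the
  # target Spearman (rho_P = 2 sin(pi rho_S / 6))
  .sim_stream(config, 8L)
  rho_p <- 2 * sin(pi * config$tmb_score_correlation / 6)
  z <- stats::qnorm((rank(latent, ties.method = "average") - 0.5) / n)
  w <- rho_p * z + sqrt(max(0, 1 - rho_p^2)) * stats::rnorm(n)
  count <- stats::qpois(stats::pnorm(w), lambda = config$mean_mutations)

  .sim_stream(config, 9L)
  pool_w <- rep(1, n_bg); pool_w[seq_len(min(20L, n_bg))] <- 5
  total <- sum(count)
  mut_gene <- sample(bg_genes, total, replace = TRUE, prob = pool_w)
  mut_class <- sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation"),
                      total, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  mutations <- data.frame(
    gene = mut_gene,
    sample_id = rep(samples, count),
    variant_classification = mut_class,
    stringsAsFactors = FALSE)

  # TRG: major response (grade 1-2) less likely the higher the latent score
  .sim_stream(config, 10L)
  p_major <- stats::plogis(-1.5 * as.numeric(scale(latent)))
  major <- stats::runif(n) < p_major
  trg <- ifelse(major, sample(1:2, n, replace = TRUE),
                sample(3:5, n, replace = TRUE))

  clinical <- validate_clinical(data.frame(
    sample_id = samples, os_time = os_time, os_event = os_event,
    age = age, sex = sex, stage = stage, trg = as.integer(trg),
    stringsAsFactors = FALSE))

  structure(list(
    expression = expression, true_fractions = F,
    true_cluster = stats::setNames(cluster, samples),
    latent = stats::setNames(latent, samples),
    signature_matrix = S, clinical = clinical, mutations = mutations,
    planted_de_genes = planted, config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples, %d genes, %d cell types, %d clusters\n",
    ncol(x$expression), nrow(x$expression), ncol(x$true_fractions),
    x$config$n_clusters))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes expression TSV, reference signature TSV, clinical TSV, a MAF, and
#' a ground-truth TSV (cluster, latent score, fractions) into a directory.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  sig <- data.frame(gene = rownames(cohort$signature_matrix),
                    cohort$signature_matrix, check.names = FALSE)
  utils::write.table(sig, file.path(dir, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_maf(cohort$mutations, file.path(dir, "mutations.maf"))
  gt <- data.frame(sample_id = rownames(cohort$true_fractions),
                   true_cluster = as.integer(cohort$true_cluster),
                   latent = as.numeric(cohort$latent),
                   cohort$true_fractions, check.names = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
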