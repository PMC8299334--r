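#' Tumor mutational burden per sample
#'
#' Mutations per megabase: the per-sample mutation count (restricted to
#' nonsynonymous classes unless \code{nonsyn_only = FALSE}) divided by the
#' interrogated coding footprint. Samples absent from the mutation table get
#' a burden of zero.
#'
#' @param m mutation table (\code{gene}, \code{sample_id},
#'   \code{variant_classification}), e.g. from \code{\link{read_maf}}.
#' @param samples character vector of sample ids to report.
#' @param exome_mb interrogated coding megabases (default 38, the standard
#'   whole-exome footprint).
#' @param nonsyn_only count only \code{\link{nonsynonymous_classes}}.
#' @return named numeric vector of TMB (mutations/Mb) per sample.
#' @export
tmb_per_sample <- function(m, samples, exome_mb = 38, nonsyn_only = TRUE) {
  stopifnot(exome_mb > 0)
  if (nonsyn_only && nrow(m))
    m <- m[m$variant_classification %in% nonsynonymous_classes, , drop = FALSE]
  counts <- table(factor(m$sample_id, levels = samples))
  stats::setNames(as.numeric(counts) / exome_mb, samples)
}

#' Mutation burden analyses against the infiltration score
#'
#' Bundles the four mutation-related comparisons: (i) two-sided Wilcoxon of
#' TMB between high and low score groups; (ii) Spearman correlation between
#' score and TMB (reported signed, with its p-value); (iii) Kaplan-Meier /
#' log-rank of TMB dichotomized at its median; (iv) log-rank across the four
#' TMB-by-score strata (df 3).
#'
#' @param scores data.frame with \code{sample_id}, \code{ici_score} and a
#'   \code{group} factor (high/low), as produced by \code{\link{ici_score}}
#'   plus \code{\link{dichotomize}}.
#' @param tmb named TMB vector covering the score samples.
#' @param clinical validated clinical table covering the score samples.
#' @return list: \code{wilcoxon}, \code{spearman} (\code{rho}, \code{p}),
#'   \code{tmb_survival}, \code{strata_survival}, \code{tmb_median}.
#' @export
tmb_analyses <- function(scores, tmb, clinical) {
  stopifnot(all(c("sample_id", "ici_score", "group") %in% colnames(scores)))
  ids <- scores$sample_id
  if (!all(ids %in% names(tmb))) stop("tmb missing some score samples")
  if (!all(ids %in% clinical$sample_id))
    stop("clinical table missing some score samples")
  tmb <- tmb[ids]
  cl <- clinical[match(ids, clinical$sample_id), ]
  wil <- group_compare(tmb, scores$group, test = "wilcoxon")
  sp <- suppressWarnings(
    stats::cor.test(scores$ici_score, tmb, method = "spearman"))
  med <- stats::median(tmb)
  tmb_group <- factor(ifelse(tmb > med, "TMB-high", "TMB-low"),
                      levels = c("TMB-low", "TMB-high"))
  tmb_surv <- logrank_test(cl$os_time, cl$os_event, tmb_group)
  strata <- interaction(tmb_group, scores$group, sep = "/", drop = FALSE)
  strata_surv <- logrank_test(cl$os_time, cl$os_event, strata)
  list(wilcoxon = wil,
       spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       tmb_survival = tmb_surv, strata_survival = strata_surv,
       tmb_median = med)
}

#' Per-group gene mutation frequency table
#'
#' For each group, the fraction of its samples carrying at least one mutation
#' in each gene (multiple hits in one sample count once), reported for the
#' \code{top_n} genes by overall frequency.
#'
#' @param m mutation table.
#' @param groups named per-sample group labels (names = sample ids; defines
#'   the sample universe, including unmutated samples).
#' @param top_n number of genes to report (default 20).
#' @return data.frame: \code{gene}, \code{overall}, one frequency column per
#'   group, ordered by decreasing overall frequency.
#' @export
mutation_summary <- function(m, groups, top_n = 20) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  samples <- names(groups)
  m <- m[m$sample_id %in% samples, , drop = FALSE]
  hits <- unique(m[, c("gene", "sample_id")])
  overall <- sort(table(hits$gene), decreasing = TRUE)
  top <- names(overall)[seq_len(min(top_n, length(overall)))]
  out <- data.frame(gene = top,
                    overall = as.numeric(overall[top]) / length(samples),
                    stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    gs <- samples[groups == g]
    sub <- hits[hits$sample_id %in% gs, , drop = FALSE]
    freq <- table(factor(sub$gene, levels = top))
    out[[as.character(g)]] <- as.numeric(freq) / length(gs)
  }
  out
}

#' Chemotherapy response class from Mandard tumor regression grade
#'
#' Grades 1-2 are major response, grades 3-5 minor response.
#'
#' @param trg integer vector of grades in 1..5.
#' @return factor with levels \code{major}, \code{minor}.
#' @export
trg_response <- function(trg) {
  if (any(is.na(trg)) || !all(trg %in% 1:5))
    stop("trg must be integers in 1..5")
  factor(ifelse(trg <= 2, "major", "minor"), levels = c("major", "minor"))
}

#' Compare the infiltration score between chemotherapy response groups
#'
#' Two-sided Wilcoxon rank-sum test of the score between major and minor
#' responders, with the direction of the median difference.
#'
#' @param scores numeric score vector.
#' @param trg_labels factor of \code{major}/\code{minor} responses (see
#'   \code{\link{trg_response}}).
#' @return list: \code{statistic}, \code{p}, \code{median_major},
#'   \code{median_minor}, \code{direction} ("major<minor", "major>minor" or
#'   "equal").
#' @export
response_compare <- function(scores, trg_labels) {
  trg_labels <- factor(trg_labels, levels = c("major", "minor"))
  if (any(table(trg_labels) == 0))
    stop("both response classes must be present")
  ht <- group_compare(scores, trg_labels, test = "wilcoxon")
  mm <- stats::median(scores[trg_labels == "major"])
  mn <- stats::median(scores[trg_labels == "minor"])
  list(statistic = ht$statistic, p = ht$p,
       median_major = mm, median_minor = mn,
       direction = if (mm < mn) "major<minor"
                   else if (mm > mn) "major>minor" else "equal")
}
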