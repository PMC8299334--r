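#' k-medoids (PAM) clustering of a distance matrix
#'
#' Partitioning around medoids. Small instances (at most 2000 candidate
#' medoid sets) are solved exactly by enumeration — the swap heuristic can
#' stall in one-swap local optima — while larger instances use greedy BUILD
#' initialization followed by steepest-descent SWAP until no swap reduces
#' the total distance of items to their cluster medoid. Fully deterministic:
#' cost ties are broken by the lowest candidate index (lexicographically
#' first medoid set on the exact path), so repeated runs agree exactly.
#'
#' @param distance symmetric non-negative matrix with zero diagonal.
#' @param k number of clusters, \code{2 <= k <= n-1}.
#' @return list with \code{labels} (1..k per item), \code{medoids} (item
#'   indices) and \code{cost} (total within-cluster distance to medoids).
#' @export
kmedoids <- function(distance, k) {
  distance <- as.matrix(distance)
  if (nrow(distance) != ncol(distance) ||
      !isTRUE(all.equal(distance, t(distance), tolerance = 1e-8)))
    stop("distance must be a symmetric matrix")
  if (any(distance < 0)) stop("distance must be non-negative")
  if (any(diag(distance) != 0)) stop("distance must have a zero diagonal")
  res <- .pam_cpp(distance, as.integer(k))
  # relabel clusters by order of first appearance for stable output
  lab <- res$labels
  relabel <- match(lab, unique(lab))
  list(labels = relabel,
       medoids = res$medoids[unique(lab)],
       cost = res$cost)
}

#' Resampled consensus clustering with PAM
#'
#' For each candidate k, repeatedly subsamples the items without replacement,
#' clusters each subsample with Euclidean PAM, and tallies how often each pair
#' of items lands in the same cluster among the rounds where both were drawn.
#' Final labels come from Ward-linkage hierarchical clustering of one minus
#' the consensus matrix, cut at k. Reports, per k, the proportion of
#' ambiguous clustering (PAC: off-diagonal consensus entries strictly inside
#' (0.1, 0.9)) and the relative change in area under the consensus CDF.
#'
#' @param features items x features numeric matrix (items are samples).
#' @param k_range integer vector of candidate cluster numbers.
#' @param n_resample subsampling rounds per k (default 500).
#' @param subsample_frac fraction of items drawn each round (default 0.8).
#' @param scale_features z-score each feature column first (use for
#'   expression features; leave off for proportions).
#' @param seed integer seed for the subsampling.
#' @return object of class \code{consensus_result}: \code{k_values},
#'   \code{consensus} (per-k matrices), \code{labels} (per-k),
#'   \code{pac}, \code{delta_area}, \code{chosen_k},
#'   \code{n_undefined} (never-co-sampled pairs, set to 0).
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_resample = 500,
                              subsample_frac = 0.8, scale_features = FALSE,
                              seed = 1) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 samples")
  if (any(!is.finite(features))) stop("features must be finite")
  if (scale_features) {
    sds <- apply(features, 2, stats::sd)
    if (all(sds == 0)) stop("all features have zero variance")
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance feature(s) dropped")
      features <- features[, sds > 0, drop = FALSE]
    }
    features <- scale(features)
  }
  n <- nrow(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("item", seq_len(n))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1)) stop("k_range out of range")
  D <- as.matrix(stats::dist(features))
  m <- ceiling(subsample_frac * n)

  consensus <- list(); labels <- list()
  pac <- numeric(length(k_range)); n_undef <- integer(length(k_range))
  areas <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    hit <- matrix(0, n, n); cnt <- matrix(0, n, n)
    set.seed((seed + 7L * k) %% .Machine$integer.max)
    for (b in seq_len(n_resample)) {
      idx <- sort(sample.int(n, m))
      lab <- kmedoids(D[idx, idx], k)$labels
      cnt[idx, idx] <- cnt[idx, idx] + 1
      for (cl in seq_len(k)) {
        members <- idx[lab == cl]
        hit[members, members] <- hit[members, members] + 1
      }
    }
    cons <- matrix(0, n, n, dimnames = list(ids, ids))
    defined <- cnt > 0
    cons[defined] <- hit[defined] / cnt[defined]
    undef <- sum(!defined[upper.tri(defined)])
    if (undef > 0)
      warning(undef, " sample pair(s) never co-sampled at k = ", k,
              "; their consensus is set to 0")
    diag(cons) <- 1
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "ward.D2")
    lab_k <- stats::cutree(hc, k = k)
    off <- cons[upper.tri(cons)]
    consensus[[ki]] <- cons
    labels[[ki]] <- stats::setNames(as.integer(lab_k), ids)
    pac[ki] <- mean(off > 0.1 & off < 0.9)
    n_undef[ki] <- undef
    # area under the consensus CDF via the standard step-sum
    sv <- sort(off)
    areas[ki] <- sum(diff(c(0, sv)) * seq_along(sv) / length(sv))
  }
  delta_area <- c(areas[1], diff(areas) / areas[-length(areas)])
  names(consensus) <- names(labels) <- paste0("k", k_range)
  res <- structure(list(
    k_values = k_range, consensus = consensus, labels = labels,
    pac = stats::setNames(pac, paste0("k", k_range)),
    delta_area = stats::setNames(delta_area, paste0("k", k_range)),
    n_undefined = stats::setNames(n_undef, paste0("k", k_range)),
    chosen_k = NA_integer_), class = "consensus_result")
  res$chosen_k <- select_k(res)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(x$k_values, collapse = ", "),
      "| chosen k =", x$chosen_k, "\n")
  print(round(x$pac, 4))
  invisible(x)
}

#' Choose the number of clusters from a consensus result
#'
#' Picks the k minimizing the proportion of ambiguous clustering; ties go to
#' the smaller k. Callers may override the choice (the reproduction path
#' fixes k = 3 for immune-infiltration clusters and k = 2 for gene clusters).
#'
#' @param result a \code{consensus_result}.
#' @return the selected integer k.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$k_values) < 2)
    return(result$k_values[1])
  result$k_values[which.min(result$pac)]
}
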