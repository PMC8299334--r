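#' Construct a cell-fraction matrix with fit diagnostics
#'
#' @param fractions samples x cell types matrix, rows summing to 1.
#' @param rmse,pearson_r,perm_p per-sample diagnostics (perm_p may be NA when
#'   no permutation test was run).
#' @return object of class \code{fraction_matrix}.
#' @export
fraction_matrix <- function(fractions, rmse, pearson_r,
                            perm_p = rep(NA_real_, nrow(fractions))) {
  stopifnot(is.matrix(fractions), !is.null(colnames(fractions)))
  if (nrow(fractions) > 0 && is.null(rownames(fractions)))
    stop("fractions must have sample rownames")
  if (any(fractions < -1e-12)) stop("fractions must be non-negative")
  rs <- rowSums(fractions)
  if (any(abs(rs - 1) > 1e-9)) stop("fraction rows must sum to 1")
  pp <- perm_p[!is.na(perm_p)]
  if (any(pp < 0 | pp > 1)) stop("perm_p must lie in [0,1]")
  structure(list(fractions = fractions, rmse = rmse, pearson_r = pearson_r,
                 perm_p = perm_p), class = "fraction_matrix")
}

#' @export
print.fraction_matrix <- function(x, ...) {
  cat(sprintf("fraction_matrix: %d samples x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

.shared_genes <- function(mixture, signature) {
  if (is.null(names(mixture))) stop("mixture must be a named vector")
  shared <- intersect(names(mixture), rownames(signature))
  if (length(shared) < 2)
    stop("mixture and signature share fewer than 2 genes")
  shared
}

#' Estimate cell-type fractions for one bulk sample
#'
#' Reference-based deconvolution of a single mixture profile against a marker
#' signature matrix. The \code{nusvr} solver follows the support-vector
#' regression design of reference-based immune deconvolution: genes restricted
#' to the signature rows, mixture and signature columns z-scored, linear-kernel
#' nu-regression fitted at nu in \{0.25, 0.5, 0.75\}, the fit with lowest
#' reconstruction RMSE kept. The \code{nnls} solver uses non-negative least
#' squares on the natural scale. Either way, negative coefficients are clipped
#' to zero and the rest renormalized to sum 1.
#'
#' @param mixture named numeric vector of expression for one sample.
#' @param signature marker genes x cell types reference matrix.
#' @param solver \code{"nnls"} or \code{"nusvr"}.
#' @return list: \code{fractions} (named, sums to 1), \code{rmse},
#'   \code{pearson_r} between reconstructed and observed mixture.
#' @export
deconvolve_sample <- function(mixture, signature, solver = c("nnls", "nusvr")) {
  solver <- match.arg(solver)
  shared <- .shared_genes(mixture, signature)
  m <- mixture[shared]
  S <- signature[shared, , drop = FALSE]
  if (all(m == 0)) stop("mixture is all-zero on the shared genes")
  k <- ncol(S)

  if (solver == "nnls") {
    coef <- .nnls_cpp(S, m)
    recon <- as.vector(S %*% coef)
    obs <- m
  } else {
    mz <- as.numeric(scale(m))
    if (any(!is.finite(mz))) stop("mixture has zero variance on shared genes")
    Sz <- scale(S)
    best <- NULL
    for (nu in c(0.25, 0.5, 0.75)) {
      fit <- e1071::svm(x = Sz, y = mz, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      w <- as.vector(t(fit$coefs) %*% fit$SV)
      pred <- as.vector(Sz %*% w) + (-fit$rho)
      r <- sqrt(mean((pred - mz)^2))
      if (is.null(best) || r < best$rmse)
        best <- list(w = w, rmse = r, pred = pred)
    }
    # w is on the column-standardized scale; map back to natural-scale
    # mixing weights before clipping/normalizing
    coef <- best$w / apply(S, 2, stats::sd)
    recon <- best$pred
    obs <- mz
  }

  coef[!is.finite(coef)] <- 0  # degenerate active set on pathological input
  coef <- pmax(coef, 0)
  if (sum(coef) == 0) {
    fractions <- rep(1 / k, k)  # degenerate fit: uninformative flat profile
  } else {
    fractions <- coef / sum(coef)
  }
  names(fractions) <- colnames(S)
  list(fractions = fractions,
       rmse = sqrt(mean((recon - obs)^2)),
       pearson_r = suppressWarnings(stats::cor(recon, obs)))
}

#' Permutation p-value for a deconvolution fit
#'
#' Deconvolves \code{n_perm} gene-label permutations of the mixture and
#' compares their reconstruction correlations with the observed one, using
#' the add-one estimator \eqn{p = (1 + \#\{r_{null} \ge r_{obs}\}) /
#' (n_{perm} + 1)} so p is never exactly zero.
#'
#' @inheritParams deconvolve_sample
#' @param n_perm number of permutations, at least 99.
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(mixture, signature, solver = c("nnls", "nusvr"),
                               n_perm = 199, seed = 1) {
  solver <- match.arg(solver)
  if (n_perm < 99) stop("n_perm must be at least 99")
  obs <- deconvolve_sample(mixture, signature, solver)$pearson_r
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample(as.numeric(mixture)), names(mixture))
    deconvolve_sample(perm, signature, solver)$pearson_r
  }, 0)
  null_r[is.na(null_r)] <- -Inf  # constant reconstruction: no correlation
  (1 + sum(null_r >= obs)) / (n_perm + 1)
}

#' Deconvolve every sample of an expression cohort
#'
#' Applies \code{\link{deconvolve_sample}} per sample, optionally with the
#' permutation filter p-value. Samples whose fit fails are dropped and their
#' error messages collected in the \code{"errors"} attribute of the result.
#'
#' @param x an \code{expr_matrix}.
#' @param signature marker genes x cell types reference.
#' @param solver \code{"nnls"} or \code{"nusvr"}.
#' @param n_perm permutations per sample for \code{\link{permutation_pvalue}};
#'   0 skips the permutation test (perm_p = NA).
#' @param seed integer seed (per-sample seeds derive from it).
#' @return a \code{\link{fraction_matrix}}.
#' @export
deconvolve_cohort <- function(x, signature, solver = c("nnls", "nusvr"),
                              n_perm = 0, seed = 1) {
  solver <- match.arg(solver)
  samples <- colnames(x)
  res <- vector("list", length(samples))
  errors <- character(0)
  for (i in seq_along(samples)) {
    mix <- stats::setNames(unclass(x)[, i], rownames(x))
    res[[i]] <- tryCatch({
      fit <- deconvolve_sample(mix, signature, solver)
      fit$perm_p <- if (n_perm > 0)
        permutation_pvalue(mix, signature, solver, n_perm,
                           seed = (seed + i) %% .Machine$integer.max)
      else NA_real_
      fit
    }, error = function(e) {
      errors[[samples[i]]] <<- conditionMessage(e)
      NULL
    })
  }
  keep <- !vapply(res, is.null, TRUE)
  if (!any(keep)) stop("deconvolution failed for every sample")
  fr <- do.call(rbind, lapply(res[keep], `[[`, "fractions"))
  rownames(fr) <- samples[keep]
  out <- fraction_matrix(
    fr,
    rmse = vapply(res[keep], `[[`, 0, "rmse"),
    pearson_r = vapply(res[keep], `[[`, 0, "pearson_r"),
    perm_p = vapply(res[keep], `[[`, 0, "perm_p"))
  attr(out, "errors") <- errors
  out
}

#' Keep samples passing the permutation filter
#'
#' Retains samples with permutation p-value below \code{alpha}, preserving
#' order — the "effective sample" filter applied before clustering.
#'
#' @param f a \code{\link{fraction_matrix}} with perm_p computed.
#' @param alpha significance threshold in (0, 1).
#' @return filtered \code{fraction_matrix}.
#' @export
filter_effective <- function(f, alpha = 0.05) {
  stopifnot(inherits(f, "fraction_matrix"), alpha > 0, alpha < 1)
  keep <- which(!is.na(f$perm_p) & f$perm_p < alpha)
  fraction_matrix(f$fractions[keep, , drop = FALSE],
                  rmse = f$rmse[keep], pearson_r = f$pearson_r[keep],
                  perm_p = f$perm_p[keep])
}
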