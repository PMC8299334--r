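#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via \code{survival::survfit}; ties are handled by
#' simultaneous events at equal times. The curve starts at 1 and is
#' non-increasing and right-continuous.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator (1 = death).
#' @return data.frame of class \code{km_curve}: \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv}.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty input")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over distinct event times (\code{survival::survdiff}), chi-squared
#' with g-1 degrees of freedom; per-group Kaplan-Meier curves are attached.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicator.
#' @param groups per-sample group labels (>= 2 non-empty groups).
#' @return list of class \code{survival_result}: \code{groups},
#'   \code{km_curves} (per group), \code{logrank_chi2}, \code{df}, \code{p},
#'   \code{n}, \code{obs}, \code{exp}.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  stopifnot(length(time) == length(event), length(groups) == length(time))
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  chi2 <- as.numeric(sd$chisq)
  km <- lapply(levels(groups), function(g)
    km_estimate(time[groups == g], event[groups == g]))
  names(km) <- levels(groups)
  structure(list(groups = levels(groups), km_curves = km,
                 logrank_chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n = as.numeric(sd$n), obs = as.numeric(sd$obs),
                 exp = as.numeric(sd$exp)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.3f, df = %d, p = %.4g (groups: %s)\n",
              x$logrank_chi2, x$df, x$p, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Optimal score cutoff by the Youden index
#'
#' Scans the midpoints of adjacent sorted unique scores as candidate
#' cutoffs and, in both classification directions (event predicted by score
#' below or above the cutoff), maximizes J = sensitivity + specificity - 1
#' against the binary event indicator. Ties are broken in favor of the
#' cutoff nearest the median score.
#'
#' @param score numeric scores.
#' @param event 0/1 outcome indicator; both classes must be present.
#' @return list: \code{cutoff}, \code{J}, \code{direction} (\code{"le"}:
#'   event predicted by score <= cutoff; \code{"gt"}: by score > cutoff).
#' @export
youden_cutoff <- function(score, event) {
  stopifnot(length(score) == length(event), all(event %in% c(0, 1)))
  if (!any(event == 1) || !any(event == 0))
    stop("both event classes must be present")
  u <- sort(unique(score))
  if (length(u) < 2) stop("scores are constant; no cutoff exists")
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- score[event == 1]; neg <- score[event == 0]
  J_le <- vapply(cand, function(c) mean(pos <= c) + mean(neg > c) - 1, 0)
  grid <- data.frame(cutoff = rep(cand, 2),
                     J = c(J_le, -J_le),
                     direction = rep(c("le", "gt"), each = length(cand)))
  best <- grid[grid$J >= max(grid$J) - 1e-12, ]
  pick <- which.min(abs(best$cutoff - stats::median(score)))
  list(cutoff = best$cutoff[pick], J = best$J[pick],
       direction = best$direction[pick])
}

#' Log-rank tests within clinical subgroups
#'
#' Repeats \code{\link{logrank_test}} of the score groups within each level
#' of a clinical splitter: age (dichotomized at \code{age_cut}), sex, or
#' stage. Levels containing fewer than two score groups are skipped with a
#' warning.
#'
#' @param clinical validated clinical data.frame (see
#'   \code{\link{validate_clinical}}).
#' @param groups per-sample score groups aligned with \code{clinical}.
#' @param by one of \code{"age"}, \code{"sex"}, \code{"stage"}.
#' @param age_cut age split in years (default 65).
#' @return named list of \code{survival_result} per subgroup level.
#' @export
subgroup_survival <- function(clinical, groups, by = c("age", "sex", "stage"),
                              age_cut = 65) {
  by <- match.arg(by)
  stopifnot(length(groups) == nrow(clinical))
  splitter <- switch(by,
    age = factor(ifelse(clinical$age <= age_cut,
                        paste0("age<=", age_cut), paste0("age>", age_cut))),
    sex = factor(clinical$sex),
    stage = factor(clinical$stage))
  out <- list()
  for (lev in levels(splitter)) {
    idx <- which(splitter == lev)
    if (length(unique(groups[idx])) < 2) {
      warning("subgroup '", lev, "' has a single score group; skipped")
      next
    }
    out[[lev]] <- logrank_test(clinical$os_time[idx], clinical$os_event[idx],
                               groups[idx])
  }
  out
}

#' Rank-based comparison of a variable between groups
#'
#' Kruskal-Wallis for two or more groups, or a two-sided Wilcoxon rank-sum
#' test for exactly two; both use mid-rank tie correction, with exact
#' enumeration for small untied two-group samples (the \code{stats} default).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param test \code{"kruskal"} or \code{"wilcoxon"}.
#' @return list: \code{statistic}, \code{p}, \code{test}.
#' @export
group_compare <- function(values, groups, test = c("kruskal", "wilcoxon")) {
  test <- match.arg(test)
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("all groups must be non-empty (>= 2 groups)")
  if (test == "kruskal") {
    ht <- stats::kruskal.test(values, groups)
  } else {
    if (nlevels(groups) != 2) stop("wilcoxon requires exactly 2 groups")
    # ties fall back to the mid-rank normal approximation; the tie warning
    # is expected behavior, not a user-facing condition
    ht <- suppressWarnings(
      stats::wilcox.test(values[groups == levels(groups)[1]],
                         values[groups == levels(groups)[2]]))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
}
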