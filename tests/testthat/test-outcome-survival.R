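test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  all_cens <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  # duplicating every subject leaves the curve unchanged
  t <- c(2, 4, 4, 7, 9); e <- c(1, 0, 1, 1, 0)
  expect_equal(km_estimate(rep(t, 2), rep(e, 2))$surv,
               km_estimate(t, e)$surv)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM curves are non-increasing and equal the empirical survival without censoring", {
  set.seed(101)
  t <- rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  expect_true(all(diff(km$surv) <= 1e-12))
  ecdf_surv <- vapply(km$time, function(x) mean(t > x), 0)
  expect_equal(km$surv, ecdf_surv)
})

test_that("log-rank matches a direct O-E / hypergeometric-variance evaluation", {
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 3)
  res <- logrank_test(time, event, grp)
  # independent evaluation: loop over distinct event times
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "A")
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == "A")
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$logrank_chi2, oe^2 / v, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(oe^2 / v, 1, lower.tail = FALSE))
})

test_that("identical groups give a null log-rank and three groups give df 2", {
  t <- c(2, 4, 7, 9, 12); e <- c(1, 1, 0, 1, 0)
  res <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 5))
  expect_equal(res$logrank_chi2, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
  set.seed(102)
  res3 <- logrank_test(rexp(30, 0.1), rbinom(30, 1, 0.7),
                       rep(c("A", "B", "C"), 10))
  expect_equal(res3$df, 2)
  expect_error(logrank_test(t, e, rep("A", 5)), "2 non-empty")
})

test_that("log-rank is invariant to monotone time transforms", {
  set.seed(103)
  t <- rexp(50, 0.05); e <- rbinom(50, 1, 0.6)
  g <- rep(c("A", "B"), 25)
  a <- logrank_test(t, e, g)
  b <- logrank_test(log1p(t), e, g)
  expect_equal(a$logrank_chi2, b$logrank_chi2, tolerance = 1e-12)
})

test_that("Youden cutoff separates a perfect toy and matches brute force", {
  res <- youden_cutoff(c(1, 2, 8, 9), c(1, 1, 0, 0))
  expect_equal(res$J, 1)
  expect_equal(res$cutoff, 5)

  worked <- youden_cutoff(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0))
  oracle <- youden_brute_force(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0))
  expect_equal(worked$cutoff, oracle$cutoff)
  expect_equal(worked$J, oracle$J)

  for (s in 1:20) {
    set.seed(110 + s)
    score <- rnorm(30)
    event <- rbinom(30, 1, 0.4)
    if (length(unique(event)) < 2) next
    mine <- youden_cutoff(score, event)
    ref <- youden_brute_force(score, event)
    expect_equal(mine$J, ref$J, tolerance = 1e-12)
    expect_equal(mine$cutoff, ref$cutoff)
  }
  expect_error(youden_cutoff(rep(1, 5), c(1, 0, 1, 0, 1)), "constant")
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both event classes")
})

test_that("null Youden J stays small at moderate n", {
  set.seed(104)
  js <- replicate(30, {
    youden_cutoff(rnorm(200), rbinom(200, 1, 0.5))$J
  })
  expect_gte(mean(js < 0.25), 0.9)
})

test_that("subgroup survival matches per-level tests and skips degenerate levels", {
  co <- generate_cohort(sim_config(n_samples = 120, seed = 105))
  cl <- co$clinical
  grp <- factor(ifelse(co$latent > median(co$latent), "high", "low"))
  by_stage <- subgroup_survival(cl, grp, by = "stage")
  for (lev in names(by_stage)) {
    idx <- cl$stage == lev
    direct <- logrank_test(cl$os_time[idx], cl$os_event[idx], grp[idx])
    expect_equal(by_stage[[lev]]$logrank_chi2, direct$logrank_chi2)
  }

  # a single-level splitter reduces to the overall test
  male <- cl; male$sex <- "male"
  by_sex <- subgroup_survival(male, grp, by = "sex")
  whole <- logrank_test(cl$os_time, cl$os_event, grp)
  expect_equal(by_sex$male$logrank_chi2, whole$logrank_chi2)

  # a level holding only one score group is skipped with a warning
  grp_one <- as.character(grp)
  grp_one[cl$sex == "female"] <- "high"
  expect_warning(res <- subgroup_survival(cl, grp_one, by = "sex"),
                 "single score group")
  expect_false("female" %in% names(res))
  expect_true("male" %in% names(res))
})

test_that("a planted hazard contrast is detected within each sex", {
  co <- generate_cohort(sim_config(n_samples = 300, seed = 106))
  cl <- co$clinical
  grp <- factor(ifelse(co$latent > median(co$latent), "high", "low"))
  by_sex <- subgroup_survival(cl, grp, by = "sex")
  expect_setequal(names(by_sex), c("male", "female"))
  for (lev in names(by_sex)) expect_lt(by_sex[[lev]]$p, 0.05)
})

test_that("group comparisons match hand-computed rank statistics", {
  # Kruskal-Wallis, no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  h <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2),
                     test = "kruskal")
  expect_equal(h$statistic, 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + 0 +
                                                  (5.5 - 3.5)^2))
  # extreme 3v3 split: exact two-sided Wilcoxon p = 2/C(6,3) = 0.1
  w <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                     test = "wilcoxon")
  expect_equal(w$p, 0.1)
  ident <- group_compare(rep(c(5, 7), 4), rep(c("a", "b"), each = 4),
                         "kruskal")
  expect_equal(ident$statistic, 0, tolerance = 1e-10)
  expect_equal(ident$p, 1, tolerance = 1e-10)
  expect_error(group_compare(1:4, c("a", "a", "b", "c"), "wilcoxon"),
               "exactly 2")
})
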