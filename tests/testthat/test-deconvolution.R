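test_that("a pure signature column deconvolves to a unit fraction", {
  S <- random_signature(30, 4, seed = 1)
  for (scale in c(1, 0.01, 250)) {
    mix <- setNames(S[, 2] * scale, rownames(S))
    fit <- deconvolve_sample(mix, S, solver = "nnls")
    expect_equal(unname(fit$fractions[2]), 1, tolerance = 1e-9)
    expect_lt(fit$rmse, 1e-6 * scale)
  }
})

test_that("two-type mixture matches the grid-search oracle", {
  set.seed(5)
  S <- matrix(exp(rnorm(8, log(100), 1)), 4, 2,
              dimnames = list(paste0("g", 1:4), c("t1", "t2")))
  truth <- c(0.3, 0.7)
  mix <- setNames(as.vector(S %*% truth), rownames(S))
  fit <- deconvolve_sample(mix, S, solver = "nnls")
  expect_equal(unname(fit$fractions), truth, tolerance = 1e-6)
  # independent oracle: exhaustive search on the simplex at step 1e-4
  f1 <- seq(0, 1, by = 1e-4)
  err <- vapply(f1, function(f) sum((S %*% c(f, 1 - f) * sum(mix) /
    sum(S %*% c(f, 1 - f)) - mix)^2), 0)
  expect_equal(unname(fit$fractions[1]), f1[which.min(err)], tolerance = 1e-4)
})

test_that("noiseless random mixtures are recovered and match pracma's NNLS", {
  skip_if_not_installed("pracma")
  for (s in 1:10) {
    S <- random_signature(25, 5, seed = s)
    truth <- random_fractions(5, seed = 100 + s)
    mix <- setNames(as.vector(S %*% truth), rownames(S))
    fit <- deconvolve_sample(mix, S, solver = "nnls")
    expect_lt(max(abs(fit$fractions - truth)), 1e-6)
    ref <- pracma::lsqnonneg(S, mix)$x
    expect_equal(unname(fit$fractions), ref / sum(ref), tolerance = 1e-6)
  }
})

test_that("fractions are invariant to mixture scale for both solvers", {
  S <- random_signature(40, 3, seed = 7)
  set.seed(8)
  mix <- setNames(as.vector(S %*% c(0.2, 0.5, 0.3)) + rnorm(40, sd = 5),
                  rownames(S))
  mix <- pmax(mix, 0)
  for (solver in c("nnls", "nusvr")) {
    f1 <- deconvolve_sample(mix, S, solver)$fractions
    f2 <- deconvolve_sample(mix * 37.5, S, solver)$fractions
    expect_equal(f1, f2, tolerance = 1e-6)
    expect_equal(sum(f1), 1)
  }
})

test_that("nusvr and nnls agree in the noiseless identifiable regime", {
  S <- random_signature(50, 4, seed = 11)
  truth <- random_fractions(4, seed = 12)
  mix <- setNames(as.vector(S %*% truth), rownames(S))
  fa <- deconvolve_sample(mix, S, "nnls")$fractions
  fb <- deconvolve_sample(mix, S, "nusvr")$fractions
  expect_lt(max(abs(fa - fb)), 0.05)
})

test_that("noise mixtures still give simplex fractions with low correlation", {
  S <- random_signature(60, 4, seed = 21)
  set.seed(22)
  rs <- replicate(20, {
    mix <- setNames(rexp(60, 1 / 100), rownames(S))
    fit <- deconvolve_sample(mix, S, "nnls")
    expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
    fit$pearson_r
  })
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("deconvolve_sample validates its inputs", {
  S <- random_signature(10, 3, seed = 3)
  expect_error(deconvolve_sample(setNames(1:1, "g1"), S), "fewer than 2")
  mix <- setNames(rep(0, 10), rownames(S))
  expect_error(deconvolve_sample(mix, S), "all-zero")
})

test_that("permutation p is minimal for a true column and validates n_perm", {
  S <- random_signature(30, 3, seed = 31)
  mix <- setNames(S[, 1], rownames(S))
  p <- permutation_pvalue(mix, S, "nnls", n_perm = 99, seed = 2)
  expect_equal(p, 1 / 100)
  expect_error(permutation_pvalue(mix, S, "nnls", n_perm = 10), "99")
})

test_that("cohort deconvolution is deterministic and near-identity on pure columns", {
  S <- random_signature(30, 3, seed = 41)
  vals <- S[, c(1, 2, 3)] %*% diag(3) # three pure samples
  colnames(vals) <- paste0("s", 1:3)
  x <- make_expr(vals)
  f <- deconvolve_cohort(x, S, "nnls", n_perm = 99, seed = 5)
  expect_equal(unname(diag(f$fractions)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(f$perm_p <= 0.05))
  f2 <- deconvolve_cohort(x, S, "nnls", n_perm = 99, seed = 5)
  expect_identical(f, f2)
})

test_that("cohort recovery: estimated fractions track the truth per cell type", {
  co <- generate_cohort(sim_config(n_samples = 100, seed = 51))
  f <- deconvolve_cohort(co$expression, co$signature_matrix, "nnls")
  est <- f$fractions[rownames(co$true_fractions), colnames(co$true_fractions)]
  rs <- vapply(seq_len(ncol(est)), function(j)
    cor(est[, j], co$true_fractions[, j]), 0)
  expect_gt(mean(rs), 0.9)
})

test_that("filter_effective applies the stated retention rule", {
  fr <- matrix(0.25, 4, 4, dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  f <- fraction_matrix(fr, rmse = rep(0.1, 4), pearson_r = rep(0.9, 4),
                       perm_p = c(0.01, 0.20, 0.04, 0.80))
  kept <- filter_effective(f, alpha = 0.05)
  expect_equal(rownames(kept$fractions), c("s1", "s3"))
  all_in <- fraction_matrix(fr, rmse = rep(0.1, 4), pearson_r = rep(0.9, 4),
                            perm_p = rep(0.001, 4))
  expect_equal(nrow(filter_effective(all_in, 0.05)$fractions), 4)
  empty <- filter_effective(f, alpha = 0.001)
  expect_equal(nrow(empty$fractions), 0)
})
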