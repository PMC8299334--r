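test_that("PAM separates well-separated clouds and validates inputs", {
  set.seed(71)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10),
               matrix(rnorm(20, 10, 0.1), 10))
  d <- as.matrix(dist(pts))
  res <- kmedoids(d, 2)
  expect_equal(length(unique(res$labels[1:10])), 1)
  expect_equal(length(unique(res$labels[11:20])), 1)
  expect_true(res$labels[1] != res$labels[11])

  expect_error(kmedoids(d, nrow(d)), "k must be")
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(kmedoids(bad, 2), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(kmedoids(neg, 2), "non-negative")
  dd <- d; diag(dd) <- 1
  expect_error(kmedoids(dd, 2), "zero diagonal")
})

test_that("PAM total cost equals the exhaustive medoid-pair minimum", {
  for (s in 1:10) {
    set.seed(700 + s)
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts))
    res <- kmedoids(d, 2)
    expect_equal(res$cost, pam_brute_force(d), tolerance = 1e-10)
  }
})

test_that("PAM agrees with cluster::pam on separated data", {
  skip_if_not_installed("cluster")
  set.seed(72)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), 15),
               matrix(rnorm(30, 6, 0.3), 15),
               matrix(rnorm(30, -6, 0.3), 15))
  d <- as.matrix(dist(pts))
  mine <- kmedoids(d, 3)
  ref <- cluster::pam(as.dist(d), 3, do.swap = TRUE)
  expect_equal(ari(mine$labels, ref$clustering), 1)
})

test_that("consensus recovers planted clusters exactly without noise", {
  co <- generate_cohort(sim_config(n_samples = 60, noise_sd = 0, seed = 73))
  cc <- consensus_cluster(co$true_fractions, k_range = 2:4,
                          n_resample = 100, seed = 3)
  expect_equal(ari(cc$labels$k3, co$true_cluster), 1)
  expect_lt(cc$pac["k3"], 0.01)
  expect_equal(cc$chosen_k, 3L)
})

test_that("consensus matrices are symmetric with unit diagonal and [0,1] entries", {
  co <- generate_cohort(sim_config(n_samples = 30, seed = 74))
  cc <- consensus_cluster(co$true_fractions, k_range = 2:3,
                          n_resample = 50, seed = 4)
  for (cons in cc$consensus) {
    expect_equal(cons, t(cons))
    expect_true(all(cons >= 0 & cons <= 1))
    expect_equal(unname(diag(cons)), rep(1, nrow(cons)))
  }
})

test_that("identical samples are always co-clustered", {
  feats <- matrix(3.7, 12, 4,
                  dimnames = list(paste0("s", 1:12), paste0("f", 1:4)))
  cc <- consensus_cluster(feats, k_range = 2, n_resample = 50, seed = 5)
  cons <- cc$consensus$k2
  expect_true(all(cons == 1 | cons == 0))
  # every pair that was ever co-sampled has consensus exactly 1
  expect_true(all(cons[cons > 0] == 1))
})

test_that("partition is invariant to sample order on separable data", {
  co <- generate_cohort(sim_config(n_samples = 40, noise_sd = 0, seed = 75))
  f <- co$true_fractions
  perm <- sample(nrow(f))
  a <- consensus_cluster(f, k_range = 3, n_resample = 80, seed = 6)
  b <- consensus_cluster(f[perm, ], k_range = 3, n_resample = 80, seed = 6)
  expect_equal(ari(a$labels$k3[rownames(f)[perm]], b$labels$k3), 1)
})

test_that("PAC counts exactly the ambiguous consensus entries", {
  # stated 4x4 example: off-diagonal entries 0.05, 0.5, 0.95, 0.5, 0.95,
  # 0.05 -> 2 of 6 lie strictly inside (0.1, 0.9)
  off <- c(0.05, 0.5, 0.95, 0.5, 0.95, 0.05)
  cons <- diag(4)
  cons[upper.tri(cons)] <- off
  cons[lower.tri(cons)] <- t(cons)[lower.tri(cons)]
  observed <- mean(cons[upper.tri(cons)] > 0.1 & cons[upper.tri(cons)] < 0.9)
  expect_equal(observed, 2 / 6)
})

test_that("select_k minimizes PAC with ties to the smaller k", {
  fake <- structure(list(k_values = c(2L, 3L, 4L),
                         pac = c(k2 = 0.30, k3 = 0.05, k4 = 0.25)),
                    class = "consensus_result")
  expect_equal(select_k(fake), 3L)
  tie <- structure(list(k_values = c(2L, 3L),
                        pac = c(k2 = 0.1, k3 = 0.1)),
                   class = "consensus_result")
  expect_equal(select_k(tie), 2L)
})

test_that("select_k recovers the planted cluster number from a 2..6 sweep", {
  co <- generate_cohort(sim_config(n_samples = 70, noise_sd = 0, seed = 76))
  cc <- consensus_cluster(co$true_fractions, k_range = 2:6,
                          n_resample = 100, seed = 7)
  expect_equal(cc$chosen_k, 3L)
})
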