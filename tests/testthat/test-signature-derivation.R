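test_that("DEG selection applies the adjusted-p and fold-change rule", {
  set.seed(81)
  n <- 20
  up <- c(rexp(n, 1 / 400) + 200, rexp(n, 1 / 40)) # strong shift, lfc > 1
  base <- seq(10, 29, length.out = n)
  weak <- c(base * 1.5, base) # clearly significant but lfc ~ 0.56 < 1
  flat <- rexp(2 * n, 1 / 50)
  vals <- rbind(UP = up, WEAK = weak, FLAT = flat)
  colnames(vals) <- paste0("s", 1:(2 * n))
  x <- expr_matrix(vals, unit = "LOG2TPM")
  labels <- rep(c("a", "b"), each = n)
  deg <- differential_genes(x, labels)
  expect_true(deg$selected[deg$gene == "UP"])
  expect_false(deg$selected[deg$gene == "WEAK"])
  expect_true(all(deg$p_adj >= deg$p))
  expect_true(all(deg$p_adj <= 1))
})

test_that("BH adjustment preserves the p-value ranking within a contrast", {
  co <- generate_cohort(sim_config(n_samples = 60, seed = 82))
  deg <- differential_genes(co$expression, co$true_cluster)
  for (ct in unique(deg$contrast)) {
    sub <- deg[deg$contrast == ct, ]
    # sorting by p must also sort p_adj: BH is rank-preserving
    expect_true(all(diff(sub$p_adj[order(sub$p)]) >= -1e-15))
    expect_true(all(sub$p_adj >= sub$p - 1e-15))
  }
})

test_that("planted differential genes are recovered and clusters validated", {
  co <- generate_cohort(sim_config(n_samples = 180, seed = 83))
  deg <- differential_genes(co$expression, co$true_cluster)
  union <- deg_union(deg)
  planted <- unlist(co$planted_de_genes)
  expect_true(all(planted %in% union))
  # false selections among truly null background genes stay rare
  null_bg <- setdiff(grep("^BG", rownames(co$expression), value = TRUE),
                     planted)
  expect_lt(mean(null_bg %in% union), 0.05)

  expect_error(differential_genes(co$expression,
                                  rep(1, ncol(co$expression))),
               "at least 2")
  bad <- co$true_cluster
  bad[bad == 2] <- 1
  bad[1:2] <- 2
  expect_error(differential_genes(co$expression, bad), "fewer than 3")
})

test_that("gene clusters recover the planted two-block structure", {
  co <- generate_cohort(sim_config(n_samples = 60, n_clusters = 2,
                                   latent_sd = 0.15, seed = 84))
  degs <- unlist(co$planted_de_genes)
  lab <- gene_clusters(co$expression, degs, k = 2, n_resample = 60, seed = 1)
  expect_equal(ari(lab, co$true_cluster), 1)

  # two duplicated bimodal genes split at the gap
  g <- c(rnorm(15, 0, 0.05), rnorm(15, 10, 0.05))
  vals <- rbind(d1 = g, d2 = g + rnorm(30, 0, 0.01))
  colnames(vals) <- paste0("s", 1:30)
  x <- expr_matrix(vals, unit = "LOG2TPM")
  lab2 <- gene_clusters(x, c("d1", "d2"), k = 2, n_resample = 60, seed = 2)
  expect_equal(length(unique(lab2[1:15])), 1)
  expect_true(lab2[1] != lab2[16])

  cn <- matrix(5, 2, 30, dimnames = list(c("c1", "c2"), paste0("s", 1:30)))
  expect_error(gene_clusters(expr_matrix(cn, unit = "LOG2TPM"),
                             c("c1", "c2")), "constant|zero variance")
  expect_error(gene_clusters(x, "d1"), "at least 2")
})

test_that("signature split follows the correlation sign and is label-symmetric", {
  co <- generate_cohort(sim_config(n_samples = 80, n_clusters = 2, seed = 85))
  degs <- unlist(co$planted_de_genes)
  lab <- co$true_cluster # ground-truth gene clusters
  pair <- split_signatures(co$expression, degs, lab, positive_cluster = 1)
  # cluster 1 sits at latent +1 so its block rises with the indicator
  expect_setequal(pair$signature_a, co$planted_de_genes$cluster1)
  expect_setequal(pair$signature_b, co$planted_de_genes$cluster2)
  swapped <- split_signatures(co$expression, degs, lab, positive_cluster = 2)
  expect_setequal(swapped$signature_a, pair$signature_b)
  expect_setequal(swapped$signature_b, pair$signature_a)
})

test_that("constant genes are dropped from the signature split with a warning", {
  vals <- rbind(up = c(1, 1, 8, 8), const = rep(3, 4))
  colnames(vals) <- paste0("s", 1:4)
  x <- expr_matrix(vals, unit = "LOG2TPM")
  lab <- setNames(c(2, 2, 1, 1), colnames(vals))
  expect_warning(pair <- split_signatures(x, c("up", "const"), lab),
                 "dropped")
  expect_equal(pair$signature_a, "up")
  expect_equal(length(pair$signature_b), 0)
})

test_that("Boruta confirms a perfect predictor and validates inputs", {
  set.seed(86)
  n <- 60
  target <- rep(c("a", "b"), each = n / 2)
  feats <- matrix(rnorm(n * 50), n,
                  dimnames = list(NULL, paste0("noise", 1:50)))
  feats <- cbind(feats, signal = as.numeric(target == "a"))
  keep <- boruta_select(feats, target, n_iter = 30, seed = 1)
  expect_true("signal" %in% keep)
  expect_true(all(keep %in% colnames(feats)))
  dec <- attr(keep, "decision")
  expect_equal(unname(dec["signal"]), "confirmed")
  expect_gt(mean(dec[paste0("noise", 1:50)] == "rejected"), 0.8)

  expect_error(boruta_select(feats, target, n_iter = 3), ">= 8")
  expect_error(boruta_select(feats, rep("a", n), n_iter = 30), "two classes")
  expect_error(boruta_select(feats[, 1:3], target, n_iter = 30),
               "at least 5")
})

test_that("Boruta is deterministic given a seed", {
  set.seed(87)
  n <- 40
  target <- rep(c("a", "b"), each = n / 2)
  feats <- matrix(rnorm(n * 20), n,
                  dimnames = list(NULL, paste0("f", 1:20)))
  feats[, 1] <- feats[, 1] + 2 * (target == "a")
  r1 <- boruta_select(feats, target, n_iter = 20, seed = 9)
  r2 <- boruta_select(feats, target, n_iter = 20, seed = 9)
  expect_identical(r1, r2)
})

test_that("signature reduction keeps the pair non-empty", {
  co <- generate_cohort(sim_config(n_samples = 60, n_clusters = 2, seed = 88))
  degs <- unlist(co$planted_de_genes)
  lab <- co$true_cluster
  pair <- split_signatures(co$expression, degs, lab)
  red <- reduce_signatures(co$expression, pair, lab, n_iter = 15,
                           num_trees = 50, seed = 3)
  expect_gt(length(red$signature_a), 0)
  expect_gt(length(red$signature_b), 0)
  expect_true(all(red$signature_a %in% pair$signature_a))
  expect_true(all(red$signature_b %in% pair$signature_b))
})
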