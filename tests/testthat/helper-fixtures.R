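# shared fixtures and small independent oracles used across test files

# adjusted Rand index (direct contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# small expression matrix with given values
make_expr <- function(values, unit = "TPM") {
  if (unit == "TPM") values <- sweep(values, 2, colSums(values), "/") * 1e6
  expr_matrix(values, unit = unit)
}

# random signature matrix for deconvolution tests
random_signature <- function(n_genes, n_types, seed) {
  set.seed(seed)
  matrix(exp(rnorm(n_genes * n_types, log(100), 1)), n_genes, n_types,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("ct", seq_len(n_types))))
}

# random point on the simplex
random_fractions <- function(k, seed) {
  set.seed(seed)
  x <- rgamma(k, 2)
  x / sum(x)
}

# naive position-by-position evaluation of the single-sample running-sum
# enrichment statistic; intentionally written as an explicit loop so it is
# independent of the package implementation
ssgsea_naive <- function(expr, set, alpha = 0.25) {
  genes <- names(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, genes)
  total_w <- sum(r[ord][genes[ord] %in% set]^alpha)
  n_out <- sum(!(genes %in% set))
  cum_in <- 0; cum_out <- 0; score <- 0
  for (i in seq_along(ord)) {
    g <- genes[ord[i]]
    if (g %in% set) cum_in <- cum_in + r[ord[i]]^alpha
    else cum_out <- cum_out + 1
    score <- score + (cum_in / total_w - cum_out / n_out)
  }
  unname(score)
}

# exhaustive k = 2 medoid search: minimum total distance over all pairs
pam_brute_force <- function(d) {
  n <- nrow(d)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(d[, i], d[, j]))
    if (cost < best) best <- cost
  }
  best
}

# exhaustive Youden search over midpoint candidates in both directions,
# with the same tie rule (cutoff nearest the median score)
youden_brute_force <- function(score, event) {
  u <- sort(unique(score))
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- score[event == 1]; neg <- score[event == 0]
  rows <- do.call(rbind, lapply(cand, function(c) {
    J_le <- mean(pos <= c) + mean(neg > c) - 1
    rbind(c(c, J_le), c(c, -J_le))
  }))
  best <- rows[rows[, 2] >= max(rows[, 2]) - 1e-12, , drop = FALSE]
  pick <- which.min(abs(best[, 1] - median(score)))
  list(cutoff = best[pick, 1], J = best[pick, 2])
}
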