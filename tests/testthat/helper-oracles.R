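# Independent brute-force oracles used to pin down the package's
# implementations. Each one is deliberately written in the most literal way
# possible (loops, enumeration) and shares no code with the package.

# Trimmed-mean-of-M-values factor of `obs` against `ref`, straight from the
# definition: M/A values on positive genes, precision weights, double trim,
# weighted mean.
oracle_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
}

# AUC by O(n^2) pair counting, ties worth one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "case" | labels == 1 | labels == TRUE]
  neg <- scores[!(labels == "case" | labels == 1 | labels == TRUE)]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by explicit summation over the overlap sizes.
oracle_ora_p <- function(k, n_set, n_universe, n_selected) {
  sizes <- k:min(n_set, n_selected)
  sum(vapply(sizes, function(i) {
    choose(n_set, i) * choose(n_universe - n_set, n_selected - i) /
      choose(n_universe, n_selected)
  }, numeric(1)))
}

# Lasso (alpha = 1) logistic-regression support by proximal gradient descent
# on the full data set; independent of glmnet's coordinate descent.
oracle_lasso_support <- function(x, y01, lambda, iters = 20000, step = NULL) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(step)) step <- 4 / max(eigen(crossprod(x) / n)$values)
  beta <- rep(0, p); b0 <- 0
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (i in seq_len(iters)) {
    eta <- b0 + x %*% beta
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(x, mu - y01) / n
    g0 <- mean(mu - y01)
    beta <- soft(beta - step * g, step * lambda)
    b0 <- b0 - step * g0
  }
  which(abs(beta) > 1e-6)
}

# Greedy nearest-age matching done longhand for tiny fixtures.
oracle_greedy_match <- function(case_ages, control_ages) {
  matched <- numeric(0)
  avail <- control_ages
  for (a in case_ages) {
    i <- which.min(abs(avail - a))
    matched <- c(matched, avail[i])
    avail <- avail[-i]
  }
  list(matched = matched, remainder = avail)
}

# Small random count fixture shared across tests.
random_counts <- function(n_genes, n_samples, mu = 80, size = 4, seed = 1) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
         nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}
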