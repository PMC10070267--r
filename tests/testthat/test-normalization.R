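test_that("identical or purely depth-scaled samples get unit TMM factors", {
  set.seed(1)
  a <- rnbinom(200, mu = 100, size = 5) + 1
  counts <- cbind(A = a, B = a)
  rownames(counts) <- sprintf("G%03d", 1:200)
  expect_equal(unname(compute_tmm_factors(counts)$tmm_factor), c(1, 1))
  counts2 <- cbind(A = a, B = 2 * a)
  rownames(counts2) <- rownames(counts)
  expect_equal(unname(compute_tmm_factors(counts2)$tmm_factor), c(1, 1))
})

test_that("TMM factor of a composition-shifted sample matches the formula oracle", {
  counts <- cbind(A = c(100, 100, 100, 100), B = c(100, 100, 100, 500))
  rownames(counts) <- paste0("g", 1:4)
  ctx <- compute_tmm_factors(counts, training_ids = "A")
  raw_b <- oracle_tmm_factor(counts[, "B"], counts[, "A"])
  # centring over the training subset {A} leaves B's factor untouched
  expect_equal(unname(ctx$tmm_factor["B"]), raw_b)
})

test_that("TMM matches edgeR's calcNormFactors when fit on all samples", {
  counts <- random_counts(300, 10, mu = 60, size = 2, seed = 7)
  ours <- compute_tmm_factors(counts)$tmm_factor
  ref <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_equal(unname(ours), ref, tolerance = 1e-10)
})

test_that("TMM factors are insensitive to any single sample's depth", {
  counts <- random_counts(200, 6, mu = 50, size = 3, seed = 11)
  ctx1 <- compute_tmm_factors(counts)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 4
  ctx2 <- compute_tmm_factors(counts2)
  # M-values are exactly depth-free; only the precision weights shift, so
  # factors agree closely (and the reference choice is unchanged)
  expect_identical(ctx1$reference_sample_id, ctx2$reference_sample_id)
  expect_equal(ctx1$tmm_factor, ctx2$tmm_factor, tolerance = 0.02)
})

test_that("training TMM factors are invariant to appending validation samples", {
  counts <- random_counts(300, 20, mu = 70, size = 2, seed = 3)
  train_ids <- colnames(counts)[1:8]
  ctx_small <- compute_tmm_factors(counts[, train_ids], training_ids = train_ids)
  ctx_full <- compute_tmm_factors(counts, training_ids = train_ids)
  expect_identical(ctx_small$reference_sample_id, ctx_full$reference_sample_id)
  expect_equal(ctx_small$tmm_factor[train_ids], ctx_full$tmm_factor[train_ids])
})

test_that("cpm_log2 applies the documented transform", {
  counts <- matrix(c(0, 999, 998001, 999), 2, 2,
                   dimnames = list(c("g1", "g2"), c("A", "B")))
  ctx <- compute_tmm_factors(counts)
  ctx$tmm_factor[] <- 1
  expr <- cpm_log2(counts, ctx)
  # count 0 with prior 1 -> 0; count 999 in a library of 999000 -> log2(1001)
  expect_equal(expr["g1", "A"], 0)
  expect_equal(expr["g2", "B"], log2(1001), tolerance = 1e-12)
  counts_b <- cbind(A = c(10, 100, 1000))
  rownames(counts_b) <- paste0("g", 1:3)
  ctx_b <- compute_tmm_factors(counts_b)
  expect_equal(cpm_log2(counts_b, ctx_b), cpm_log2(2 * counts_b, ctx_b))
})

test_that("RUV factor scores are orthonormal and track a planted batch", {
  set.seed(21)
  expr <- matrix(rnorm(200 * 30), 200, 30,
                 dimnames = list(sprintf("G%03d", 1:200), sprintf("S%02d", 1:30)))
  batch <- rep(c(0, 1), each = 15)
  expr <- expr + outer(rnorm(200, 0, 1.5), batch)
  m <- fit_ruv(expr, k = 4)
  expect_lt(max(abs(crossprod(m$scores) - diag(4))), 1e-8)
  expect_gt(abs(cor(m$scores[, 1], batch)), 0.9)
  # reconstruction: loadings %*% t(scores) at full rank reproduces the
  # centred matrix restricted to the leading subspace
  recon <- m$loadings %*% t(m$scores)
  centred <- expr - rowMeans(expr)
  expect_lt(max(abs(recon - centred)) / max(abs(centred)), 0.9)
})

test_that("k = 0 RUV model leaves the matrix unchanged", {
  expr <- matrix(rnorm(50 * 10), 50, 10,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  m <- fit_ruv(expr, k = 0)
  res <- select_and_remove_ruv_factors(expr, m, rep(c("case", "control"), 5),
                                       data.frame(age = rnorm(10)))
  expect_identical(res$expr, expr)
  expect_error(fit_ruv(expr, k = -1), "non-negative")
})

test_that("dual-threshold rule removes batch factors and protects class factors", {
  set.seed(33)
  n <- 40
  expr <- matrix(rnorm(300 * n), 300, n,
                 dimnames = list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:n)))
  batch <- rep(c(0, 1), each = n / 2)               # orthogonal to class
  class <- rep(c("case", "control"), n / 2)          # alternating
  expr_b <- expr + outer(rnorm(300, 0, 2), batch)
  m <- fit_ruv(expr_b, k = 3)
  conf <- data.frame(hospital = factor(batch))
  res <- select_and_remove_ruv_factors(expr_b, m, class, conf)
  sel <- res$model$selection
  expect_true(sel$removed[1])
  expect_gt(sel$p_class[1], 0.01)
  expect_lt(sel$p_confounder_min[1], 0.01)
  # corrected data has almost no between-batch variance left
  batch_share <- function(e) {
    d <- rowMeans(e[, batch == 1]) - rowMeans(e[, batch == 0])
    mean(d^2)
  }
  expect_lt(batch_share(res$expr), 0.1 * batch_share(expr_b))

  # a factor aligned with class is retained even if batch-associated
  expr_c <- expr + outer(rnorm(300, 0, 2), as.numeric(class == "case"))
  m2 <- fit_ruv(expr_c, k = 3)
  res2 <- select_and_remove_ruv_factors(expr_c, m2, class,
                                        data.frame(hospital = factor(batch)))
  expect_false(res2$model$selection$removed[1])
})

test_that("when no factor qualifies the corrected matrix is exactly the input", {
  set.seed(5)
  expr <- matrix(rnorm(100 * 20), 100, 20,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:20)))
  m <- fit_ruv(expr, k = 3)
  res <- select_and_remove_ruv_factors(expr, m, rep(c("case", "control"), 10),
                                       data.frame(age = rnorm(20)),
                                       p_confounder_threshold = 1e-12)
  expect_false(any(res$model$removed))
  expect_identical(res$expr, expr)
})

test_that("RUV removal is a projection: applying it twice changes nothing", {
  set.seed(14)
  expr <- matrix(rnorm(150 * 24), 150, 24,
                 dimnames = list(paste0("g", 1:150), paste0("s", 1:24)))
  batch <- rep(c(0, 1), each = 12)
  expr <- expr + outer(rnorm(150, 0, 2), batch)
  m <- fit_ruv(expr, k = 4)
  res <- select_and_remove_ruv_factors(expr, m, rep(c("case", "control"), 12),
                                       data.frame(hospital = factor(batch)))
  once <- apply_ruv_correction(expr, res$model)
  twice <- apply_ruv_correction(once, res$model)
  expect_equal(once, twice, tolerance = 1e-10)
})

test_that("RUV loadings fitted on training are reused, not refit, for new samples", {
  set.seed(44)
  expr <- matrix(rnorm(120 * 30), 120, 30,
                 dimnames = list(paste0("g", 1:120), paste0("s", 1:30)))
  m_train <- fit_ruv(expr[, 1:20], k = 3)
  sc <- ruv_scores(m_train, expr)
  expect_equal(sc[1:20, ], unname(m_train$scores[, ]), ignore_attr = TRUE)
  # projection of the training samples equals their SVD scores
  colnames(expr) <- paste0("x", 1:30)
  sc_proj <- ruv_scores(m_train, expr[, 1:20])
  expect_equal(unname(sc_proj), unname(m_train$scores), tolerance = 1e-10)
})
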