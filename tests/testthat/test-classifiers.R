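# Small expression fixture with a few informative genes.
make_expr_fixture <- function(n_genes = 30, n_per_class = 15, shift_genes = 3,
                              shift = 4, seed = 1) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%03d", seq_len(2 * n_per_class))))
  labels <- rep(c("case", "control"), each = n_per_class)
  expr[seq_len(shift_genes), labels == "case"] <-
    expr[seq_len(shift_genes), labels == "case"] + shift
  list(expr = expr, labels = labels)
}

test_that("gene ranking follows the Welch statistic with deterministic ties", {
  fx <- make_expr_fixture()
  rk <- rank_candidate_genes(fx$expr, fx$labels)
  expect_setequal(rk$gene_id[1:3], c("G001", "G002", "G003"))
  # brute-force Welch t oracle
  oracle_t <- apply(fx$expr, 1, function(y) {
    t.test(y[fx$labels == "case"], y[fx$labels == "control"])$statistic
  })
  ord <- order(-abs(oracle_t), names(oracle_t))
  expect_identical(rk$gene_id, names(oracle_t)[ord])
  expect_error(rank_candidate_genes(fx$expr, rep("case", 30)), "Both classes")
})

test_that("PSO solves a 2-D sphere far better than its initial sampling", {
  sphere <- function(p) sum(p^2)
  cfg <- pso_config(n_particles = 100, n_iterations = 10,
                    bounds = list(x = c(-5, 5), y = c(-5, 5)),
                    integer_dims = character(0), seed = 5)
  res <- pso_optimize(sphere, cfg)
  expect_lt(res$best_fitness, 0.01)
  expect_true(all(diff(res$trace) <= 1e-12))
  # random search with the same evaluation budget does clearly worse
  set.seed(5)
  rnd <- min(replicate(1100, sphere(runif(2, -5, 5))))
  expect_lt(res$best_fitness, rnd)
})

test_that("PSO contract cases: constant objective, degenerate swarm, penalty", {
  cfg1 <- pso_config(n_particles = 10, n_iterations = 3,
                     bounds = list(x = c(0, 1)), integer_dims = character(0),
                     seed = 2)
  expect_equal(pso_optimize(function(p) 0.3, cfg1)$best_fitness, 0.3)
  # one particle with zero acceleration just evaluates its initial position
  cfg2 <- pso_config(n_particles = 1, n_iterations = 5,
                     bounds = list(x = c(-1, 1)), w = 0.5, c1 = 0, c2 = 0,
                     integer_dims = character(0), seed = 3)
  seen <- new.env(); seen$x <- c()
  obj <- function(p) { seen$x <- c(seen$x, p); abs(p) }
  res <- pso_optimize(obj, cfg2)
  expect_equal(length(unique(round(seen$x, 12))), 1)
  expect_equal(res$best_fitness, unname(abs(seen$x[1])))
  # non-finite objective values are penalised, not fatal
  res3 <- pso_optimize(function(p) NaN, cfg1)
  expect_equal(res3$best_fitness, 1)
})

test_that("elastic net separates a separable toy and degenerates with lambda", {
  fx <- make_expr_fixture(n_genes = 10, shift_genes = 2, shift = 6)
  m <- train_elastic_net(fx$expr, fx$labels, alpha_grid = c(0.5, 1), seed = 2)
  pred <- predict_proba(m, fx$expr)
  expect_equal(roc_auc(fx$labels, pred$score), 1)
  # infinite penalty keeps only the intercept
  x <- t(fx$expr)
  y <- factor(fx$labels, levels = c("control", "case"))
  big <- glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = 1e6)
  expect_true(all(abs(as.numeric(coef(big))[-1]) < 1e-12))
  # nonzero count non-increasing in lambda at alpha = 1
  path <- glmnet::glmnet(x, y, family = "binomial", alpha = 1)
  nz <- colSums(abs(as.matrix(path$beta)) > 0)
  expect_true(all(diff(nz[order(path$lambda)]) <= 0))
})

test_that("lasso support matches an independent proximal-gradient oracle", {
  set.seed(11)
  n <- 40; p <- 20
  x <- matrix(rnorm(n * p), n, p)
  beta_true <- c(2, -2, 1.5, rep(0, p - 3))
  y01 <- rbinom(n, 1, plogis(x %*% beta_true))
  lambda <- 0.08
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE, thresh = 1e-12)
  support_glmnet <- which(abs(as.numeric(fit$beta)) > 1e-6)
  support_oracle <- oracle_lasso_support(x, y01, lambda)
  expect_identical(support_glmnet, support_oracle)
  expect_true(all(1:3 %in% support_glmnet))
})

test_that("down-sampling balances classes inside the CV loop", {
  fx <- make_expr_fixture(n_genes = 12, n_per_class = 20, shift = 5)
  # make it imbalanced 30/10
  keep <- c(which(fx$labels == "case"), which(fx$labels == "control")[1:10])
  expr <- fx$expr[, keep]; labels <- fx$labels[keep]
  m <- train_elastic_net(expr, labels, balance = "downsample",
                         alpha_grid = c(1), nfolds = 5, seed = 4)
  expect_s3_class(m, "tep_classifier")
  pred <- predict_proba(m, expr)
  expect_gt(roc_auc(labels, pred$score), 0.9)
})

test_that("LOOCV elastic net runs and stores the scheme", {
  fx <- make_expr_fixture(n_genes = 8, n_per_class = 8, shift = 5)
  m <- suppressWarnings(train_elastic_net(fx$expr, fx$labels, cv_scheme = "loocv",
                                          alpha_grid = c(0.5), seed = 6))
  expect_equal(m$cv_scheme, "loocv")
  expect_gt(m$cv_auc, 0.9)
})

test_that("PSO-SVM learns a separable synthetic cohort", {
  design <- tibble::tibble(hospital = c("A", "B"),
                           n_cases = c(30L, 30L), n_controls = c(30L, 30L))
  meta <- build_confounded_design(design, seed = 8)
  cfg <- sim_config(n_genes = 300, case_effect_sd = 0.6,
                    gene_modules = list(platelet_activation = 1:40,
                                        biomarker = 41:80))
  counts <- simulate_counts(meta, cfg, seed = 8)
  meta <- partition_samples(meta, partition_config(seed = 8))
  m <- train_pso_svm(counts, meta,
                     pso = pso_config(n_particles = 8, n_iterations = 3, seed = 8))
  id_int <- meta$sample_id[meta$partition == "internal_validation"]
  pred <- predict_proba(m, counts[, id_int])
  lab <- meta$group[match(id_int, meta$sample_id)]
  expect_gte(roc_auc(lab, pred$score), 0.95)
  # stored gene count respects the searched bounds
  expect_gte(length(m$genes), m$pso$bounds$n_genes[1])
  expect_lte(length(m$genes), m$pso$bounds$n_genes[2])
  # prediction is deterministic and bounded
  pred2 <- predict_proba(m, counts[, id_int])
  expect_identical(pred, pred2)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("label-permuted training yields chance-level internal performance", {
  design <- tibble::tibble(hospital = "A", n_cases = 40L, n_controls = 40L)
  meta <- build_confounded_design(design, seed = 21)
  cfg <- sim_config(n_genes = 200, case_effect_sd = 0, hospital_effect_sd = 0,
                    gene_modules = list(platelet_activation = 1:20,
                                        biomarker = 21:40))
  counts <- simulate_counts(meta, cfg, seed = 21)
  aucs <- sapply(1:3, function(s) {
    set.seed(s)
    meta_p <- meta
    meta_p$group <- sample(meta_p$group)
    meta_p$stage[meta_p$group == "case"] <- "II"
    meta_p$stage[meta_p$group == "control"] <- NA
    meta_p <- partition_samples(meta_p, partition_config(seed = s))
    m <- train_pso_svm(counts, meta_p,
                       pso = pso_config(n_particles = 5, n_iterations = 2, seed = s))
    id_int <- meta_p$sample_id[meta_p$partition == "internal_validation"]
    pred <- predict_proba(m, counts[, id_int])
    roc_auc(meta_p$group[match(id_int, meta_p$sample_id)], pred$score)
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("prediction refuses gene-incomplete input and never reads labels", {
  design <- tibble::tibble(hospital = "A", n_cases = 12L, n_controls = 12L)
  meta <- build_confounded_design(design, seed = 30)
  cfg <- sim_config(n_genes = 180, case_effect_sd = 0.8,
                    gene_modules = list(platelet_activation = 1:20,
                                        biomarker = 21:60))
  counts <- simulate_counts(meta, cfg, seed = 30)
  meta <- partition_samples(meta, partition_config(seed = 30))
  msv <- train_pso_svm(counts, meta,
                       pso = pso_config(n_particles = 4, n_iterations = 2, seed = 30))
  expect_error(predict_proba(msv, counts[1:50, ]), "missing")
  expect_false("group" %in% names(predict_proba(msv, counts)))
})
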