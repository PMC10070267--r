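#' Rank candidate biomarker genes by a two-sample statistic
#'
#' Genes are ordered by decreasing absolute Welch t-statistic between cases
#' and controls; ties are broken by gene identifier so the ranking is
#' deterministic.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Case/control label per sample.
#' @return Tibble `gene_id`, `statistic`, `rank` in rank order.
#' @export
rank_candidate_genes <- function(expr, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) abort("Both classes need at least two samples.")
  x1 <- expr[, pos, drop = FALSE]; x0 <- expr[, !pos, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, var); v0 <- apply(x0, 1, var)
  se <- sqrt(v1 / n1 + v0 / n0)
  t_stat <- (m1 - m0) / se
  t_stat[!is.finite(t_stat)] <- 0
  ord <- order(-abs(t_stat), rownames(expr))
  tibble(gene_id = rownames(expr)[ord],
         statistic = t_stat[ord],
         rank = seq_along(ord))
}

#' Particle swarm optimisation configuration
#'
#' @param n_particles,n_iterations Swarm size and number of update
#'   iterations (defaults 100 and 10, the published classifier protocol).
#' @param bounds Named list of length-2 numeric ranges, one per searched
#'   dimension.
#' @param w Inertia weight; `c1`, `c2` cognitive and social acceleration
#'   (defaults 0.72 / 1.49 / 1.49, the standard constriction values).
#' @param integer_dims Names of dimensions rounded to integers at
#'   evaluation time.
#' @param seed RNG seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 100, n_iterations = 10,
                       bounds = list(p_class = c(0.001, 0.2),
                                     p_confounder = c(0.001, 0.2),
                                     n_genes = c(5, 200),
                                     log2_cost = c(-5, 10),
                                     log2_gamma = c(-12, 2)),
                       w = 0.72, c1 = 1.49, c2 = 1.49,
                       integer_dims = "n_genes", seed = 1L) {
  stopifnot(n_particles >= 1, n_iterations >= 1, length(bounds) >= 1)
  for (b in bounds) stopifnot(length(b) == 2, b[2] > b[1])
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 bounds = bounds, w = w, c1 = c1, c2 = c2,
                 integer_dims = integer_dims, seed = as.integer(seed)),
            class = "pso_config")
}

round_integer_dims <- function(x, cfg) {
  ix <- names(cfg$bounds) %in% cfg$integer_dims
  x[ix] <- round(x[ix])
  x
}

#' Global-best particle swarm optimisation
#'
#' Canonical PSO: velocities are updated as
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, positions as
#' `x <- x + v` and clamped to the bounds. Positions in integer dimensions
#' are rounded before each objective evaluation. Objectives returning a
#' non-finite value are penalised with fitness 1. The trace of the global
#' best fitness is non-increasing; the result is deterministic given the
#' seed.
#'
#' @param objective Function taking a named numeric position, returning a
#'   scalar fitness to minimise (here usually 1 - AUC).
#' @param cfg A [pso_config()].
#' @return List with `best_position`, `best_fitness`, `trace` (global best
#'   after initialisation and after each iteration).
#' @export
pso_optimize <- function(objective, cfg = pso_config()) {
  stopifnot(inherits(cfg, "pso_config"))
  set.seed(cfg$seed)
  d <- length(cfg$bounds)
  lo <- vapply(cfg$bounds, `[`, numeric(1), 1)
  hi <- vapply(cfg$bounds, `[`, numeric(1), 2)
  np <- cfg$n_particles
  pos <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, dimnames = list(NULL, names(cfg$bounds)))
  vel <- matrix(0, np, d)
  eval_at <- function(x) {
    f <- tryCatch(objective(round_integer_dims(x, cfg)), error = function(e) NA_real_)
    if (!is.finite(f)) 1 else f
  }
  fit <- apply(pos, 1, eval_at)
  pbest <- pos; pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]; gbest_fit <- fit[g]
  trace <- gbest_fit
  for (it in seq_len(cfg$n_iterations)) {
    r1 <- matrix(runif(np * d), np, d)
    r2 <- matrix(runif(np * d), np, d)
    gb <- matrix(gbest, np, d, byrow = TRUE)
    vel <- cfg$w * vel + cfg$c1 * r1 * (pbest - pos) + cfg$c2 * r2 * (gb - pos)
    pos <- pos + vel
    pos <- pmin(pmax(pos, rep(lo, each = np)), rep(hi, each = np))
    fit <- apply(pos, 1, eval_at)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, ]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit) {
      gbest_fit <- pbest_fit[g]
      gbest <- pbest[g, ]
    }
    trace <- c(trace, gbest_fit)
  }
  list(best_position = round_integer_dims(gbest, cfg),
       best_fitness = gbest_fit, trace = trace)
}

# RBF-SVM with an explicit Platt probability layer: a logistic regression of
# the training labels on the SVM decision values. Learning the sigmoid's sign
# from the data avoids the decision-value orientation ambiguity of the
# underlying libsvm fit.
svm_platt_fit <- function(x, y, cost, gamma) {
  fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  f <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                       "decision.values"))
  df <- data.frame(y01 = as.integer(y == "case"), f = f)
  platt <- suppressWarnings(glm(y01 ~ f, family = stats::binomial(), data = df))
  b <- coef(platt)
  b[is.na(b)] <- 0
  list(svm = fit, platt_intercept = unname(b[1]), platt_slope = unname(b[2]))
}

svm_platt_predict <- function(model, x_new) {
  f <- as.numeric(attr(predict(model$svm, x_new, decision.values = TRUE),
                       "decision.values"))
  plogis(model$platt_intercept + model$platt_slope * f)
}

# The RUV nuisance-variable frame used throughout: age, library size and
# hospital of origin.
ruv_confounders <- function(meta, counts) {
  data.frame(age = meta$age,
             lib_size = colSums(counts)[meta$sample_id],
             hospital = factor(meta$hospital))
}

#' Train the particle-swarm-optimised SVM classifier
#'
#' Implements the published TEP classifier protocol: the swarm searches the
#' two RUV retention thresholds, the number of top-ranked biomarker genes
#' and the RBF-SVM cost and gamma, minimising 1 - AUC on the evaluation
#' partition. For each particle, candidate RUV factors (fitted once by SVD
#' on the training + evaluation expression) are selected with the
#' particle's thresholds and regressed out; genes are re-ranked on the
#' corrected training expression; an RBF SVM with Platt-scaled probability
#' outputs is fitted on the training samples and scored on the evaluation
#' samples. The normalisation context (subset-aware TMM with the reference
#' drawn from the training partition) and the RUV model are fitted on
#' training + evaluation samples only and stored in the returned model, so
#' prediction on new samples is a pure function of the model and their
#' counts.
#'
#' @param counts QC-filtered count matrix.
#' @param meta Metadata with `sample_id`, `group`, `hospital`, `age`,
#'   `partition`.
#' @param pso A [pso_config()].
#' @param ruv_k Number of candidate RUV factors (default
#'   `min(10, n_samples - 1)`).
#' @return A `tep_classifier` of kind `"pso_svm"`.
#' @export
train_pso_svm <- function(counts, meta, pso = pso_config(), ruv_k = NULL) {
  check_counts(counts)
  meta <- check_meta(meta)
  if (!"partition" %in% names(meta)) abort("`meta` needs a `partition` column.")
  id_train <- meta$sample_id[meta$partition == "training"]
  id_eval <- meta$sample_id[meta$partition == "evaluation"]
  if (!length(id_train) || !length(id_eval)) {
    abort("Training and evaluation partitions must be non-empty.")
  }
  lab <- setNames(meta$group, meta$sample_id)
  if (length(unique(lab[id_eval])) < 2 || length(unique(lab[id_train])) < 2) {
    abort("Training and evaluation partitions must contain both classes.")
  }
  dev_ids <- c(id_train, id_eval)
  counts_dev <- counts[, dev_ids, drop = FALSE]
  meta_dev <- meta[match(dev_ids, meta$sample_id), ]
  ctx <- compute_tmm_factors(counts_dev, training_ids = id_train)
  expr <- cpm_log2(counts_dev, ctx)
  if (is.null(ruv_k)) ruv_k <- min(10, ncol(expr) - 1)
  ruv <- fit_ruv(expr, k = ruv_k)
  conf <- ruv_confounders(meta_dev, counts_dev)
  y_train <- factor(lab[id_train], levels = c("control", "case"))
  y_eval <- lab[id_eval]
  fit_particle <- function(p) {
    sel <- suppressWarnings(
      select_and_remove_ruv_factors(expr, ruv, meta_dev$group, conf,
                                    p_class_threshold = p[["p_class"]],
                                    p_confounder_threshold = p[["p_confounder"]]))
    n_genes <- max(2L, min(as.integer(p[["n_genes"]]), nrow(expr)))
    ranking <- rank_candidate_genes(sel$expr[, id_train, drop = FALSE], y_train)
    genes <- ranking$gene_id[seq_len(n_genes)]
    svm_fit <- svm_platt_fit(t(sel$expr[genes, id_train, drop = FALSE]),
                             y_train,
                             cost = 2^p[["log2_cost"]],
                             gamma = 2^p[["log2_gamma"]])
    c(svm_fit, list(genes = genes, ruv = sel$model, expr = sel$expr))
  }
  objective <- function(p) {
    m <- fit_particle(p)
    pr <- svm_platt_predict(m, t(m$expr[m$genes, id_eval, drop = FALSE]))
    1 - roc_auc(y_eval, pr)
  }
  opt <- pso_optimize(objective, pso)
  best <- fit_particle(opt$best_position)
  structure(list(kind = "pso_svm",
                 genes = best$genes,
                 svm = best$svm,
                 platt_intercept = best$platt_intercept,
                 platt_slope = best$platt_slope,
                 ctx = ctx, ruv = best$ruv,
                 best_position = opt$best_position,
                 best_fitness = opt$best_fitness,
                 trace = opt$trace,
                 pso = pso,
                 partitions = list(training = id_train, evaluation = id_eval),
                 seed = pso$seed),
            class = "tep_classifier")
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

downsample_idx <- function(idx, y) {
  tab <- table(y[idx])
  n_min <- min(tab)
  unlist(lapply(names(tab), function(cl) {
    cl_idx <- idx[y[idx] == cl]
    if (length(cl_idx) > n_min) sample(cl_idx, n_min) else cl_idx
  }))
}

#' Train the elastic-net baseline classifier
#'
#' Penalised logistic regression over an (alpha, lambda) grid, selected by
#' cross-validated AUC. For each alpha, the lambda path is taken from a fit
#' on all samples, each fold's model is fitted on the remaining folds
#' (optionally after down-sampling the majority class within the loop) and
#' scored on the held-out fold; held-out predictions are pooled into one
#' AUC per (alpha, lambda). The coefficients at the best grid point are
#' refitted on all provided samples. Leave-one-out cross-validation is the
#' k = n special case.
#'
#' @param expr Expression matrix (genes x samples), typically TMM-cpm-log2
#'   without RUV correction.
#' @param labels Case/control label per sample.
#' @param cv_scheme `"kfold"` (default, 10 folds) or `"loocv"`.
#' @param balance `"none"` or `"downsample"` (majority class subsampled
#'   inside each cross-validation loop).
#' @param alpha_grid Mixing parameters searched.
#' @param nfolds Number of folds for `"kfold"`.
#' @param nlambda Length of each lambda path.
#' @param seed RNG seed (fold assignment, down-sampling).
#' @param ctx Optional `norm_context` stored in the model so that new
#'   samples can be normalised at prediction time.
#' @param ruv Optional selected `ruv_model` applied before prediction.
#' @return A `tep_classifier` of kind `"elastic_net"`.
#' @export
train_elastic_net <- function(expr, labels, cv_scheme = c("kfold", "loocv"),
                              balance = c("none", "downsample"),
                              alpha_grid = seq(0, 1, 0.1), nfolds = 10,
                              nlambda = 50, seed = 1L, ctx = NULL, ruv = NULL) {
  cv_scheme <- match.arg(cv_scheme)
  balance <- match.arg(balance)
  pos <- as_binary_labels(labels)
  y <- factor(ifelse(pos, "case", "control"), levels = c("control", "case"))
  x <- t(expr)
  n <- nrow(x)
  k <- if (cv_scheme == "loocv") n else nfolds
  if (n < k) abort("Fewer samples than folds.")
  if (cv_scheme == "kfold") {
    fold <- stratified_folds(y, k, seed)
    if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
      abort("Each fold must contain both classes.")
    }
  } else {
    fold <- seq_len(n)
  }
  set.seed(seed + 1L)
  grid <- purrr::map_dfr(alpha_grid, function(a) {
    full <- glmnet::glmnet(x, y, family = "binomial", alpha = a, nlambda = nlambda)
    lam <- full$lambda
    pred <- matrix(NA_real_, n, length(lam))
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      if (balance == "downsample") tr <- downsample_idx(tr, y)
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = a, lambda = lam)
      pred[fold == f, ] <- predict(fit, x[fold == f, , drop = FALSE],
                                   type = "response", s = lam)
    }
    auc <- apply(pred, 2, function(p) roc_auc(y, p))
    tibble(alpha = a, lambda = lam, cv_auc = auc)
  })
  best <- grid[which.max(grid$cv_auc), ]
  final <- glmnet::glmnet(x, y, family = "binomial", alpha = best$alpha,
                          lambda = best$lambda)
  beta <- as.numeric(coef(final))
  names(beta) <- rownames(coef(final))
  nz <- names(beta)[-1][beta[-1] != 0]
  structure(list(kind = "elastic_net",
                 intercept = beta[1],
                 coefficients = beta[-1],
                 genes = if (length(nz)) nz else names(beta)[-1],
                 alpha = best$alpha, lambda = best$lambda,
                 cv_auc = best$cv_auc, cv_grid = grid,
                 cv_scheme = cv_scheme, balance = balance,
                 ctx = ctx, ruv = ruv, seed = seed),
            class = "tep_classifier")
}

#' Predict case probabilities for new samples
#'
#' New samples are normalised with the stored training-derived context
#' (subset-aware TMM against the stored reference, cpm-log2, and -- for the
#' PSO-SVM or an RUV-equipped elastic net -- projection onto the stored RUV
#' loadings and removal of the selected factors). No part of the model is
#' re-fitted and labels of the new samples are never read, so the output is
#' a pure function of the model and the counts.
#'
#' @param model A `tep_classifier`.
#' @param counts_new Count matrix over the model's genes (all genes of the
#'   training matrix must be present).
#' @return Tibble `sample_id`, `score` (probability of "case").
#' @export
predict_proba <- function(model, counts_new) {
  stopifnot(inherits(model, "tep_classifier"), is.matrix(counts_new))
  if (ncol(counts_new) == 0) abort("No samples to predict.")
  if (is.null(model$ctx)) {
    # model trained directly on expression; counts_new must be expression
    expr <- counts_new
  } else {
    check_counts(counts_new)
    if (!identical(rownames(counts_new), model$ctx$gene_ids)) {
      missing <- setdiff(model$ctx$gene_ids, rownames(counts_new))
      if (length(missing)) {
        abort(sprintf("New samples are missing %d model genes (e.g. %s).",
                      length(missing), missing[1]))
      }
      counts_new <- counts_new[model$ctx$gene_ids, , drop = FALSE]
    }
    expr <- cpm_log2(counts_new, model$ctx)
  }
  if (!is.null(model$ruv)) expr <- apply_ruv_correction(expr, model$ruv)
  if (model$kind == "pso_svm") {
    pr <- svm_platt_predict(model, t(expr[model$genes, , drop = FALSE]))
  } else {
    eta <- model$intercept + as.numeric(t(expr[names(model$coefficients), ,
                                               drop = FALSE]) %*% model$coefficients)
    pr <- plogis(eta)
  }
  tibble(sample_id = colnames(counts_new), score = unname(pr))
}

#' @export
print.tep_classifier <- function(x, ...) {
  cat(sprintf("TEP classifier (%s): %d genes\n", x$kind, length(x$genes)))
  if (x$kind == "pso_svm") {
    cat(sprintf("  evaluation-set AUC at optimum: %.3f\n", 1 - x$best_fitness))
  } else {
    cat(sprintf("  alpha %.2f, lambda %.4g, cross-validated AUC %.3f\n",
                x$alpha, x$lambda, x$cv_auc))
  }
  invisible(x)
}

#' @export
tidy.tep_classifier <- function(x, ...) {
  if (x$kind == "elastic_net") {
    tibble(gene_id = names(x$coefficients), estimate = unname(x$coefficients)) |>
      dplyr::filter(.data$estimate != 0) |>
      dplyr::arrange(dplyr::desc(abs(.data$estimate)))
  } else {
    tibble(gene_id = x$genes, rank = seq_along(x$genes))
  }
}

#' @export
glance.tep_classifier <- function(x, ...) {
  if (x$kind == "elastic_net") {
    tibble(kind = x$kind, n_genes = length(x$genes), alpha = x$alpha,
           lambda = x$lambda, cv_auc = x$cv_auc)
  } else {
    tibble(kind = x$kind, n_genes = length(x$genes),
           eval_auc = 1 - x$best_fitness,
           n_ruv_removed = sum(x$ruv$removed))
  }
}

#' Save / load a trained classifier
#'
#' @param model A `tep_classifier`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tep_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "tep_classifier"))
  m
}
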