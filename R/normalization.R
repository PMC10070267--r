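#' Subset-aware TMM normalisation factors
#'
#' Computes trimmed-mean-of-M-values scaling factors in which both the
#' reference sample and the geometric-mean centring are derived from a
#' designated subset of samples (typically the training partition). Factors
#' for any other sample are computed against that fixed reference, so adding
#' or removing validation samples can never change the factors of the
#' training samples -- the no-leakage property required when a normalisation
#' context learned on training data is applied to held-out or external
#' batches.
#'
#' The reference is the training sample whose upper-quartile relative
#' expression is closest to the training mean upper-quartile. Each sample's
#' factor is \eqn{2^{\bar M_w}}, the weighted trimmed mean of per-gene
#' M-values against the reference, with weights the inverse asymptotic
#' binomial variances, trimming `trim_m` of M-values on each tail and
#' `trim_a` of A-values; factors are then divided by their geometric mean
#' over the training subset.
#'
#' @param counts Count matrix (genes x samples).
#' @param training_ids Sample ids from which reference and centring are
#'   derived; defaults to all samples (plain TMM).
#' @param trim_m,trim_a Two-tail trim proportions for M- and A-values
#'   (defaults 0.30 and 0.05).
#' @param prior_count Pseudo-expression added inside the log2-cpm transform.
#' @return A `norm_context` with the reference profile, per-sample factors
#'   and the parameters needed to normalise unseen samples.
#' @export
compute_tmm_factors <- function(counts, training_ids = colnames(counts),
                                trim_m = 0.30, trim_a = 0.05,
                                prior_count = 1) {
  check_counts(counts)
  training_ids <- as.character(training_ids)
  if (length(training_ids) == 0) abort("`training_ids` must be non-empty.")
  if (!all(training_ids %in% colnames(counts))) {
    abort("All `training_ids` must be columns of `counts`.")
  }
  lib <- colSums(counts)
  train <- counts[, training_ids, drop = FALSE]
  lib_train <- lib[training_ids]
  if (any(lib_train == 0)) abort("A training sample has zero library size.")
  f75 <- vapply(seq_along(training_ids),
                function(j) quantile(train[, j] / lib_train[j], 0.75, names = FALSE),
                numeric(1))
  ref_id <- training_ids[which.min(abs(f75 - mean(f75)))]
  ref <- counts[, ref_id]
  n_ref <- lib[[ref_id]]
  raw <- vapply(colnames(counts), function(s) {
    tmm_pair_factor(counts[, s], lib[[s]], ref, n_ref, trim_m, trim_a)
  }, numeric(1))
  centring <- exp(mean(log(raw[training_ids])))
  structure(list(reference_sample_id = ref_id,
                 ref_counts = ref, ref_libsize = n_ref,
                 tmm_factor = raw / centring, centring = centring,
                 trim_m = trim_m, trim_a = trim_a,
                 prior_count = prior_count,
                 training_sample_ids = training_ids,
                 gene_ids = rownames(counts),
                 lib_sizes = lib),
            class = "norm_context")
}

# Weighted trimmed mean of M-values of one sample against a fixed reference.
# Follows the classical TMM estimator: precision weights from the delta-method
# variance of an M-value, double trimming on M and A.
tmm_pair_factor <- function(obs, n_obs, ref, n_ref, trim_m, trim_a) {
  if (n_obs == 0) abort("Sample has zero library size.")
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep2 <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  if (!any(keep2)) return(1)
  f <- sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM factor for samples not present in a normalisation context
#'
#' @param ctx A `norm_context` from [compute_tmm_factors()].
#' @param counts_new Count matrix of new samples over the same genes.
#' @return Named numeric vector of factors on the context's centring scale.
#' @export
tmm_factors_for <- function(ctx, counts_new) {
  stopifnot(inherits(ctx, "norm_context"))
  if (!identical(rownames(counts_new), ctx$gene_ids)) {
    abort("New samples must carry exactly the context's genes, in order.")
  }
  lib <- colSums(counts_new)
  raw <- vapply(seq_len(ncol(counts_new)), function(j) {
    tmm_pair_factor(counts_new[, j], lib[j], ctx$ref_counts, ctx$ref_libsize,
                    ctx$trim_m, ctx$trim_a)
  }, numeric(1))
  setNames(raw / ctx$centring, colnames(counts_new))
}

#' TMM-scaled log2 counts-per-million
#'
#' `log2(count / (libsize * factor) * 1e6 + prior_count)`. Stored factors
#' are used for samples present in the context; factors for unseen samples
#' are computed against the stored reference without touching the context.
#'
#' @param counts Count matrix.
#' @param ctx A `norm_context`; defaults to plain TMM on `counts`.
#' @return Expression matrix, genes x samples.
#' @export
cpm_log2 <- function(counts, ctx = compute_tmm_factors(counts)) {
  check_counts(counts)
  stopifnot(inherits(ctx, "norm_context"))
  if (!identical(rownames(counts), ctx$gene_ids)) {
    abort("`counts` genes do not match the normalisation context.")
  }
  ids <- colnames(counts)
  fac <- setNames(rep(NA_real_, length(ids)), ids)
  known <- ids[ids %in% names(ctx$tmm_factor)]
  fac[known] <- ctx$tmm_factor[known]
  unknown <- ids[!ids %in% known]
  if (length(unknown)) {
    fac[unknown] <- tmm_factors_for(ctx, counts[, unknown, drop = FALSE])
  }
  lib <- colSums(counts)
  eff <- lib * fac
  if (any(eff <= 0)) abort("Zero effective library size.")
  log2(sweep(counts, 2, eff, `/`) * 1e6 + ctx$prior_count)
}

#' Estimate unwanted-variation factors by singular value decomposition
#'
#' Centres each gene across the provided samples and takes the first `k`
#' singular components: factor scores are the orthonormal right singular
#' vectors (samples x k), loadings are \eqn{U D} (genes x k). Scores for
#' samples outside the fitting set are obtained by projection
#' ([ruv_scores()]), never by re-fitting.
#'
#' @param expr Expression matrix (genes x samples), typically log2 cpm.
#' @param k Number of candidate factors; `k = 0` gives an empty model.
#' @return A `ruv_model`.
#' @export
fit_ruv <- function(expr, k = min(10, ncol(expr) - 1)) {
  if (k < 0) abort("`k` must be non-negative.")
  if (k >= min(dim(expr))) abort("`k` must be smaller than both matrix dimensions.")
  gene_means <- rowMeans(expr)
  centred <- expr - gene_means
  if (k == 0) {
    return(structure(list(k = 0L, scores = matrix(0, ncol(expr), 0),
                          loadings = matrix(0, nrow(expr), 0), d = numeric(0),
                          gene_means = gene_means, gene_ids = rownames(expr),
                          sample_ids = colnames(expr), removed = logical(0),
                          selection = NULL),
                     class = "ruv_model"))
  }
  sv <- svd(centred, nu = k, nv = k)
  structure(list(k = as.integer(k),
                 scores = matrix(sv$v, ncol = k, dimnames = list(colnames(expr), NULL)),
                 loadings = sv$u %*% diag(sv$d[seq_len(k)], k),
                 d = sv$d[seq_len(k)],
                 gene_means = gene_means, gene_ids = rownames(expr),
                 sample_ids = colnames(expr),
                 removed = rep(FALSE, k), selection = NULL),
            class = "ruv_model")
}

#' Factor scores for arbitrary samples under a fitted RUV model
#'
#' Scores are always obtained by projecting the (training-mean-centred)
#' expression onto the fitted loadings, never by re-fitting; for the
#' samples the model was fitted on this reproduces their SVD scores. Being
#' a pure function of the data, the projection also makes factor removal
#' idempotent: a corrected matrix projects to zero on the removed
#' components.
#'
#' @param model A `ruv_model`.
#' @param expr Expression matrix over the model's genes.
#' @return samples x k score matrix.
#' @export
ruv_scores <- function(model, expr) {
  stopifnot(inherits(model, "ruv_model"))
  if (!identical(rownames(expr), model$gene_ids)) {
    abort("`expr` genes do not match the RUV model.")
  }
  if (model$k == 0) return(matrix(0, ncol(expr), 0, dimnames = list(colnames(expr), NULL)))
  centred <- expr - model$gene_means
  out <- t(centred) %*% (model$loadings %*% diag(1 / model$d^2, model$k))
  dimnames(out) <- list(colnames(expr), NULL)
  out
}

# p-value for association between a factor score vector and one variable.
# Binary / categorical variables: two-sample t-test (each level vs rest for
# >2 levels, minimum p). Continuous variables: t-test of the regression slope.
score_assoc_p <- function(score, x) {
  if (sd(score) == 0) return(NA_real_)
  if (is.numeric(x) && length(unique(x)) > 2) {
    fit <- summary(lm(score ~ x))
    return(fit$coefficients["x", "Pr(>|t|)"])
  }
  x <- as.factor(x)
  levs <- levels(x)
  if (length(levs) < 2) return(NA_real_)
  if (length(levs) == 2) levs <- levs[1]
  ps <- vapply(levs, function(l) {
    g <- x == l
    if (sum(g) < 2 || sum(!g) < 2) return(NA_real_)
    tryCatch(t.test(score[g], score[!g])$p.value, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
}

#' Select and remove unwanted-variation factors (dual-threshold rule)
#'
#' A candidate factor is regressed out of the expression matrix iff both
#' (a) its association p-value with case-control status exceeds
#' `p_class_threshold` (it does not carry class signal) and (b) its
#' association p-value with at least one nuisance variable (age, library
#' size, hospital of origin) is below `p_confounder_threshold` (it does
#' carry unwanted variation). The corrected matrix is
#' `expr - loadings[, removed] %*% t(scores[, removed])`: an orthogonal
#' projection, so applying the same selection twice changes nothing.
#'
#' @param expr Expression matrix (genes x samples).
#' @param model A `ruv_model` fitted on (a superset of) these samples.
#' @param class_labels "case"/"control" per sample.
#' @param confounders Data frame of nuisance variables aligned to samples
#'   (e.g. hospital, age, lib_size).
#' @param p_class_threshold,p_confounder_threshold The two retention
#'   thresholds (defaults 0.01 and 0.01).
#' @return List with `expr` (corrected matrix) and `model` (with `removed`
#'   mask and the per-factor p-value table in `$selection`).
#' @export
select_and_remove_ruv_factors <- function(expr, model, class_labels, confounders,
                                          p_class_threshold = 0.01,
                                          p_confounder_threshold = 0.01) {
  stopifnot(inherits(model, "ruv_model"))
  if (length(class_labels) != ncol(expr)) abort("`class_labels` must align with samples.")
  confounders <- as.data.frame(confounders)
  if (nrow(confounders) != ncol(expr)) abort("`confounders` must align with samples.")
  if (model$k == 0) {
    return(list(expr = expr, model = model))
  }
  scores <- ruv_scores(model, expr)
  sel <- purrr::map_dfr(seq_len(model$k), function(j) {
    s <- scores[, j]
    if (sd(s) == 0) {
      warn(sprintf("RUV factor %d is constant; skipped.", j))
      return(tibble(factor = j, p_class = NA_real_, p_confounder_min = NA_real_,
                    removed = FALSE))
    }
    p_class <- score_assoc_p(s, factor(class_labels))
    p_conf <- vapply(confounders, function(x) score_assoc_p(s, x), numeric(1))
    p_min <- if (all(is.na(p_conf))) NA_real_ else min(p_conf, na.rm = TRUE)
    removed <- !is.na(p_class) && !is.na(p_min) &&
      p_class > p_class_threshold && p_min < p_confounder_threshold
    tibble(factor = j, p_class = p_class, p_confounder_min = p_min, removed = removed)
  })
  model$removed <- sel$removed
  model$selection <- sel
  model$p_class_threshold <- p_class_threshold
  model$p_confounder_threshold <- p_confounder_threshold
  list(expr = apply_ruv_correction(expr, model, scores), model = model)
}

#' Apply a fitted, selected RUV correction to an expression matrix
#'
#' @param expr Expression matrix over the model's genes (any samples).
#' @param model A `ruv_model` whose `removed` mask has been set.
#' @param scores Optional precomputed score matrix.
#' @return Corrected expression matrix.
#' @export
apply_ruv_correction <- function(expr, model, scores = NULL) {
  stopifnot(inherits(model, "ruv_model"))
  if (model$k == 0 || !any(model$removed)) return(expr)
  if (is.null(scores)) scores <- ruv_scores(model, expr)
  rm <- which(model$removed)
  expr - model$loadings[, rm, drop = FALSE] %*% t(scores[, rm, drop = FALSE])
}

#' @export
tidy.ruv_model <- function(x, ...) {
  if (is.null(x$selection)) {
    tibble(factor = seq_len(x$k), singular_value = x$d,
           removed = if (length(x$removed)) x$removed else rep(FALSE, x$k))
  } else {
    dplyr::mutate(x$selection, singular_value = x$d[.data$factor], .after = "factor")
  }
}

#' @export
glance.ruv_model <- function(x, ...) {
  tibble(k = x$k, n_removed = sum(x$removed), n_samples = length(x$sample_ids),
         n_genes = length(x$gene_ids))
}

#' @export
print.norm_context <- function(x, ...) {
  cat(sprintf("TMM normalisation context: reference %s, %d training samples, %d factors\n",
              x$reference_sample_id, length(x$training_sample_ids), length(x$tmm_factor)))
  invisible(x)
}
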