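#' Named experiment recipes
#'
#' Two stock study conditions for transfer experiments:
#'
#' * `recipe_confounded()` -- the skewed multicentre design of
#'   [confounded_design()] with the calibrated hospital batch effect on the
#'   platelet-activation module but only a weak case-control effect
#'   (`case_effect_sd = 0.05`): almost all of the separation a classifier
#'   can find runs through the hospital module, which is confounded with
#'   case-control status. The external batch comes from a new centre with a
#'   freshly drawn batch vector.
#' * `recipe_unconfounded()` -- the balanced [balanced_design()] with the
#'   default (strong, calibrated) case effect; the external batch re-uses
#'   the training centres' batch vectors, i.e. is drawn from the same
#'   distribution.
#'
#' @return List with `design`, `cfg`, `external_design`, `fresh_batch`.
#' @export
recipe_confounded <- function() {
  list(design = confounded_design(),
       cfg = sim_config(case_effect_sd = 0.05),
       external_design = tibble(hospital = "EXT", n_cases = 37L, n_controls = 36L),
       fresh_batch = TRUE)
}

#' @rdname recipe_confounded
#' @export
recipe_unconfounded <- function() {
  d <- balanced_design()
  list(design = d,
       cfg = sim_config(),
       external_design = dplyr::mutate(d,
                                       n_cases = c(13L, 12L, 12L),
                                       n_controls = c(12L, 12L, 12L)),
       fresh_batch = FALSE)
}

#' Train on a recipe and validate on its external batch
#'
#' Runs [run_multicentre_experiment()] under a recipe's study conditions,
#' simulates the recipe's external validation batch and evaluates every
#' trained classifier on both the internal validation partition and the
#' external batch.
#'
#' @param recipe Output of [recipe_confounded()] / [recipe_unconfounded()].
#' @param seed Master seed.
#' @param pso A [pso_config()].
#' @param classifiers Classifiers to train.
#' @return Tibble with one row per classifier and set (`internal_validation`
#'   all-stage row, `external_validation`).
#' @export
run_transfer_experiment <- function(recipe, seed = 1L,
                                    pso = pso_config(n_particles = 20,
                                                     n_iterations = 5),
                                    classifiers = c("pso_svm", "elastic_net")) {
  exp <- run_multicentre_experiment(design = recipe$design, cfg = recipe$cfg,
                                    pso = pso, classifiers = classifiers,
                                    seed = seed)
  ext <- simulate_external_batch(exp, external_design = recipe$external_design,
                                 fresh_batch = recipe$fresh_batch)
  internal <- dplyr::filter(exp$metrics, .data$stage_group == "all")
  internal <- dplyr::select(internal, -"stage_group")
  external <- run_blinded_validation(exp, ext)
  dplyr::bind_rows(internal, external)
}

#' Run the multicentre training / internal-validation experiment
#'
#' End-to-end orchestration on synthetic data: build the (possibly
#' confounded) sample sheet, simulate counts, run QC, partition samples
#' (stage-stratified case split, age-matched controls), fit the
#' normalisation context on the development samples, train the requested
#' classifiers and evaluate them on the internal validation partition,
#' including early/late stage strata. Every stage derives its seed from
#' `seed`, so the whole experiment is reproducible.
#'
#' @param design Per-hospital design table (default [confounded_design()]).
#' @param cfg A [sim_config()].
#' @param qc A [qc_config()].
#' @param pso A [pso_config()]; pass a reduced swarm for quick experiments.
#' @param classifiers Character subset of `c("pso_svm", "elastic_net")`.
#' @param en_alpha_grid Alpha grid for the elastic net.
#' @param ruv_k Candidate RUV factors for the PSO-SVM.
#' @param seed Master seed.
#' @return A `tep_experiment` list: `meta`, `counts`, `qc`, `models`,
#'   `predictions`, `metrics`, `effects`, configs and seed.
#' @export
run_multicentre_experiment <- function(design = confounded_design(),
                                       cfg = sim_config(),
                                       qc = qc_config(),
                                       pso = pso_config(n_particles = 20,
                                                        n_iterations = 5),
                                       classifiers = c("pso_svm", "elastic_net"),
                                       en_alpha_grid = seq(0, 1, 0.25),
                                       ruv_k = NULL,
                                       seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  meta <- build_confounded_design(design, age_range = cfg$age_range, seed = seed)
  effects <- sim_gene_effects(cfg, seed = seed + 1000L)
  counts <- simulate_counts(meta, cfg, seed = seed + 2000L, effects = effects)
  effects <- attr(counts, "effects")
  qc_res <- run_qc(counts, qc)
  counts_qc <- qc_res$counts
  meta <- meta[meta$sample_id %in% colnames(counts_qc), ]
  meta <- partition_samples(meta, partition_config(seed = seed + 3000L))
  meta$lib_size <- colSums(counts_qc)[meta$sample_id]
  lab <- setNames(meta$group, meta$sample_id)
  id_int <- meta$sample_id[meta$partition == "internal_validation"]
  models <- list()
  predictions <- list()
  metrics <- list()
  pso <- pso_config(n_particles = pso$n_particles, n_iterations = pso$n_iterations,
                    bounds = pso$bounds, w = pso$w, c1 = pso$c1, c2 = pso$c2,
                    integer_dims = pso$integer_dims, seed = seed + 4000L)
  if ("pso_svm" %in% classifiers) {
    models$pso_svm <- train_pso_svm(counts_qc, meta, pso = pso, ruv_k = ruv_k)
  }
  if ("elastic_net" %in% classifiers) {
    dev_ids <- meta$sample_id[meta$partition %in% c("training", "evaluation")]
    id_train <- meta$sample_id[meta$partition == "training"]
    ctx <- compute_tmm_factors(counts_qc[, dev_ids, drop = FALSE],
                               training_ids = id_train)
    expr_dev <- cpm_log2(counts_qc[, dev_ids, drop = FALSE], ctx)
    models$elastic_net <- train_elastic_net(expr_dev, lab[dev_ids],
                                            alpha_grid = en_alpha_grid,
                                            seed = seed + 5000L, ctx = ctx)
  }
  for (nm in names(models)) {
    pred <- predict_proba(models[[nm]], counts_qc[, id_int, drop = FALSE])
    predictions[[nm]] <- pred
    metrics[[nm]] <- dplyr::mutate(evaluate_predictions(pred, meta),
                                   classifier = nm, set = "internal_validation",
                                   .before = 1)
  }
  structure(list(meta = meta, counts = counts_qc, qc = qc_res,
                 models = models, predictions = predictions,
                 metrics = dplyr::bind_rows(metrics),
                 effects = effects,
                 config = list(design = design, cfg = cfg, qc = qc, pso = pso,
                               en_alpha_grid = en_alpha_grid),
                 seed = seed),
            class = "tep_experiment")
}

#' Simulate an external validation batch for a fitted experiment
#'
#' Draws a new sample set with the gene effects of the training simulation.
#' With `fresh_batch = TRUE` (the default) the external centre receives a
#' newly drawn batch-effect vector -- modelling the observation that every
#' new collection batch effectively represents a new distribution. Using
#' hospital ids already present in the training design reuses their stored
#' batch vectors instead (a same-distribution external set).
#'
#' @param experiment A `tep_experiment`.
#' @param external_design Design table for the external batch; the default
#'   is a single new centre with 37 cases and 36 controls.
#' @param fresh_batch Draw a new batch vector for unseen hospital ids.
#' @param seed RNG seed.
#' @return List with `counts` (over the experiment's QC-filtered genes),
#'   `meta` and `labels`.
#' @export
simulate_external_batch <- function(experiment,
                                    external_design = tibble(hospital = "EXT",
                                                             n_cases = 37L,
                                                             n_controls = 36L),
                                    fresh_batch = TRUE,
                                    seed = experiment$seed + 9000L) {
  stopifnot(inherits(experiment, "tep_experiment"))
  cfg <- experiment$config$cfg
  meta_ext <- build_confounded_design(external_design, age_range = cfg$age_range,
                                      seed = seed, id_prefix = "E")
  effects <- experiment$effects
  if (!fresh_batch) {
    known <- names(effects$hospital_effects)
    if (!all(meta_ext$hospital %in% known)) {
      abort("With `fresh_batch = FALSE` the external design must reuse training hospitals.")
    }
  }
  counts_ext <- simulate_counts(meta_ext, cfg, seed = seed + 1L, effects = effects)
  counts_ext <- counts_ext[rownames(experiment$counts), , drop = FALSE]
  list(counts = counts_ext,
       meta = dplyr::select(meta_ext, -"group"),
       labels = dplyr::select(meta_ext, "sample_id", "group"))
}

#' Blinded prediction step
#'
#' Computes per-sample case probabilities without any access to class
#' labels; the returned table deliberately contains no label column.
#'
#' @param model A `tep_classifier` (or a path to one saved with
#'   [write_model()]).
#' @param counts Count matrix of the blinded samples.
#' @return Tibble `sample_id`, `score`.
#' @export
predict_blinded <- function(model, counts) {
  if (is.character(model)) model <- read_model(model)
  predict_proba(model, counts)
}

#' Link blinded predictions to true labels and evaluate
#'
#' The unblinding step: joins the prediction table to a label table (as an
#' independent third party would) and computes performance metrics. Errors
#' if any predicted sample has no label or vice versa.
#'
#' @param predictions Output of [predict_blinded()].
#' @param labels Tibble `sample_id`, `group`.
#' @param threshold,ci_level Passed to [confusion_metrics()].
#' @return A `tep_metrics` row.
#' @export
link_and_evaluate <- function(predictions, labels, threshold = 0.5,
                              ci_level = 0.95) {
  predictions <- as_tibble(predictions)
  labels <- as_tibble(labels)
  if ("group" %in% names(predictions)) {
    abort("Prediction table must not contain labels before linking.")
  }
  if (!setequal(predictions$sample_id, labels$sample_id)) {
    abort("Sample ids of predictions and labels do not match.")
  }
  df <- dplyr::inner_join(predictions, labels, by = "sample_id")
  confusion_metrics(df$group, df$score, threshold, ci_level)
}

#' Blinded external validation of trained classifiers
#'
#' Convenience wrapper running the two blinded-validation invocations in
#' sequence for every model of an experiment: [predict_blinded()] on the
#' external counts, then [link_and_evaluate()] against the label table.
#'
#' @param experiment A `tep_experiment`.
#' @param external Output of [simulate_external_batch()] (or a list with
#'   `counts`, `labels`).
#' @return Tibble of metrics rows, one per classifier.
#' @export
run_blinded_validation <- function(experiment, external) {
  purrr::imap_dfr(experiment$models, function(model, nm) {
    pred <- predict_blinded(model, external$counts)
    dplyr::mutate(link_and_evaluate(pred, external$labels),
                  classifier = nm, set = "external_validation", .before = 1)
  })
}

#' @export
print.tep_experiment <- function(x, ...) {
  cat("TEP multicentre experiment\n")
  cat(sprintf("  samples: %d (post-QC), genes: %d\n", nrow(x$meta), nrow(x$counts)))
  sizes <- table(x$meta$partition, x$meta$group)
  print(sizes)
  m <- dplyr::filter(x$metrics, .data$stage_group == "all")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %s internal-validation AUC: %.3f (%.3f-%.3f)\n",
                m$classifier[i], m$auc[i], m$ci_low[i], m$ci_high[i]))
  }
  invisible(x)
}

#' @export
tidy.tep_experiment <- function(x, ...) x$metrics

#' @export
glance.tep_experiment <- function(x, ...) {
  m <- dplyr::filter(x$metrics, .data$stage_group == "all")
  tibble(n_samples = nrow(x$meta), n_genes = nrow(x$counts),
         n_training = sum(x$meta$partition == "training"),
         n_evaluation = sum(x$meta$partition == "evaluation"),
         n_internal_validation = sum(x$meta$partition == "internal_validation"),
         classifiers = paste(m$classifier, collapse = ","),
         best_internal_auc = max(m$auc))
}

#' @export
autoplot.tep_experiment <- function(object, ...) {
  lab <- setNames(object$meta$group, object$meta$sample_id)
  preds <- purrr::map(object$predictions, function(p) {
    list(labels = lab[p$sample_id], scores = p$score)
  })
  plot_roc(preds) + labs(title = "Internal validation ROC")
}

#' Partition size summary of an experiment
#'
#' @param experiment A `tep_experiment`.
#' @return Tibble `partition`, `group`, `n`.
#' @export
partition_sizes <- function(experiment) {
  dplyr::count(experiment$meta, .data$partition, .data$group, name = "n")
}
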