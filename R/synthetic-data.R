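#' Simulation configuration for synthetic platelet RNA-seq counts
#'
#' Bundles the parameters of the negative-binomial count generator that
#' emulates a confounded multicentre platelet RNA-seq study: a hospital
#' batch effect concentrated in a "platelet activation"-like gene module, a
#' disjoint case-control biomarker module, log-normal sequencing depth,
#' and optional erythrocyte/lymphocyte marker contamination.
#'
#' Counts are gamma-Poisson: for gene g in sample s the mean is
#' \eqn{\mu_{gs} = p_{gs} \cdot d_s} where \eqn{d_s} is the sample's depth and
#' \eqn{p_{gs}} the relative abundance obtained by renormalising
#' \eqn{2^{b_g + h_{gs} + c_{gs}}} within the sample; the variance is
#' \eqn{\mu + \mu^2 \phi} with dispersion \eqn{\phi}. Hospital effects
#' \eqn{h} act only on the batch module (one vector per hospital, drawn once
#' per simulation), case effects \eqn{c} only on the biomarker module.
#'
#' The default effect magnitudes are calibrated so that, on the default
#' confounded design at around 300 samples, a per-gene mixed-model variance
#' decomposition attributes roughly 19\% of module-gene variance to hospital
#' of origin and 14\% to case-control status, with the remainder residual --
#' the regime reported for real multicentre platelet cohorts.
#'
#' @param n_genes Number of genes.
#' @param gene_modules Named list of integer gene indices. Recognised names:
#'   `platelet_activation` (batch-affected module), `biomarker`
#'   (case-control module; must be disjoint from the batch module),
#'   `haemoglobin_markers`, `lymphocyte_markers` (contamination targets).
#' @param baseline_log_mean_range Interval (log2 scale) for baseline relative
#'   expression. Module genes are drawn from the upper half of the interval
#'   so that they survive coverage filtering, as abundant platelet
#'   transcripts do.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi} (> 0).
#' @param hospital_effect_sd SD (log2) of per-hospital effects on the batch
#'   module.
#' @param case_effect_sd SD (log2) of per-gene case effects on the biomarker
#'   module.
#' @param libsize_log_sd SD of log sequencing depth.
#' @param depth_mean Mean intron-spanning read depth per sample.
#' @param age_range Age interval (years) used by [build_confounded_design()].
#' @param contamination_rate Fraction of samples receiving marker spiking.
#' @param contamination_strength Multiplier applied to marker-gene means of
#'   contaminated samples.
#' @param target_variance_fractions Intended (hospital, case, residual)
#'   variance shares; stored for reporting, not enforced.
#' @param seed Default RNG seed recorded in the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       gene_modules = default_gene_modules(n_genes),
                       baseline_log_mean_range = c(1, 8),
                       nb_dispersion = 0.15,
                       hospital_effect_sd = 0.33,
                       case_effect_sd = 0.38,
                       libsize_log_sd = 0.4,
                       depth_mean = 2e6,
                       age_range = c(35, 70),
                       contamination_rate = 0,
                       contamination_strength = 5,
                       target_variance_fractions = c(hospital = 0.19, case = 0.14, residual = 0.67),
                       seed = 1L) {
  stopifnot(n_genes >= 1, nb_dispersion > 0, libsize_log_sd >= 0,
            depth_mean > 0, contamination_rate >= 0, contamination_rate <= 1,
            contamination_strength > 0, length(baseline_log_mean_range) == 2,
            diff(baseline_log_mean_range) > 0)
  if (any(target_variance_fractions < 0) || any(target_variance_fractions > 1) ||
      sum(target_variance_fractions[c("hospital", "case")]) > 1) {
    abort("`target_variance_fractions` must lie in [0,1] and sum to at most 1.")
  }
  for (nm in names(gene_modules)) {
    idx <- gene_modules[[nm]]
    if (length(idx) && (any(idx < 1) || any(idx > n_genes))) {
      abort(sprintf("Gene module '%s' has indices outside 1..n_genes.", nm))
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), gene_modules = gene_modules,
         baseline_log_mean_range = baseline_log_mean_range,
         nb_dispersion = nb_dispersion,
         hospital_effect_sd = hospital_effect_sd,
         case_effect_sd = case_effect_sd,
         libsize_log_sd = libsize_log_sd, depth_mean = depth_mean,
         age_range = age_range,
         contamination_rate = contamination_rate,
         contamination_strength = contamination_strength,
         target_variance_fractions = target_variance_fractions,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default gene-module layout
#'
#' @param n_genes Total number of genes; must accommodate the modules.
#' @return Named list of gene index vectors.
#' @export
default_gene_modules <- function(n_genes = 1000) {
  if (n_genes < 170) abort("Default gene modules need at least 170 genes.")
  list(platelet_activation = 1:100,
       biomarker = 101:150,
       haemoglobin_markers = 151:158,
       lymphocyte_markers = 159:166)
}

#' Stylised confounded multicentre design
#'
#' A three-centre case-control design in which controls are dominated by one
#' centre while cases come mostly from the other two -- the skew that makes
#' hospital of origin a confounder of case-control status in multicentre
#' platelet studies. Per-hospital counts are a stylised skew, not a
#' reconstruction of any real cohort.
#'
#' @return Tibble with columns `hospital`, `n_cases`, `n_controls`.
#' @export
confounded_design <- function() {
  tibble(hospital  = c("H1", "H2", "H3"),
         n_cases   = c(6L, 70L, 64L),
         n_controls = c(100L, 30L, 10L))
}

#' Balanced (unconfounded) multicentre design
#'
#' Same total sizes as [confounded_design()] but with cases and controls
#' contributed evenly by every centre, so hospital and case-control status
#' are independent.
#'
#' @return Tibble with columns `hospital`, `n_cases`, `n_controls`.
#' @export
balanced_design <- function() {
  tibble(hospital  = c("H1", "H2", "H3"),
         n_cases   = c(47L, 47L, 46L),
         n_controls = c(47L, 47L, 46L))
}

#' Build sample metadata for a (possibly confounded) case-control design
#'
#' Expands a per-hospital design table into one metadata row per sample,
#' drawing ages uniformly from `age_range` and assigning tumour stages to
#' cases with probabilities `stage_probs`.
#'
#' @param design Tibble/data frame with columns `hospital`, `n_cases`,
#'   `n_controls` (one row per centre).
#' @param age_range Numeric length-2 age interval in years.
#' @param stage_probs Named probabilities over stages I--IV for cases; the
#'   default mirrors the stage mix of a screening-age breast-cancer cohort.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param id_prefix Prefix for generated sample ids.
#' @return Tibble with columns `sample_id`, `group`, `hospital`, `age`,
#'   `stage` (NA for controls).
#' @export
build_confounded_design <- function(design,
                                    age_range = c(35, 70),
                                    stage_probs = c(I = 0.14, II = 0.48, III = 0.13, IV = 0.25),
                                    seed = 1L,
                                    id_prefix = "S") {
  design <- as_tibble(design)
  if (nrow(design) == 0) abort("Design table is empty.")
  if (!all(c("hospital", "n_cases", "n_controls") %in% names(design))) {
    abort("Design table needs columns hospital, n_cases, n_controls.")
  }
  if (any(design$n_cases < 0) || any(design$n_controls < 0)) {
    abort("Per-hospital counts must be non-negative.")
  }
  if (sum(design$n_cases) == 0 || sum(design$n_controls) == 0) {
    abort("Design must contribute at least one case and one control.")
  }
  set.seed(seed)
  rows <- purrr::pmap_dfr(design, function(hospital, n_cases, n_controls, ...) {
    tibble(hospital = hospital,
           group = rep(c("case", "control"), c(n_cases, n_controls)))
  })
  n <- nrow(rows)
  rows$sample_id <- sprintf("%s%04d", id_prefix, seq_len(n))
  rows$age <- round(runif(n, age_range[1], age_range[2]), 1)
  rows$stage <- NA_character_
  n_case <- sum(rows$group == "case")
  rows$stage[rows$group == "case"] <-
    sample(names(stage_probs), n_case, replace = TRUE, prob = stage_probs)
  rows[, c("sample_id", "group", "hospital", "age", "stage")]
}

#' Draw gene-level simulation effects
#'
#' Baseline log2 abundances and the module effect vectors used by
#' [simulate_counts()]. Keeping the effects object separate from the count
#' draw lets several sample sets (e.g. a later external validation batch)
#' share the same genes while new hospitals receive fresh batch-effect
#' vectors -- each new collection batch is a new distribution.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed.
#' @return A `sim_effects` list with `base`, `case_effect` and (initially
#'   empty) per-hospital effect vectors.
#' @export
sim_gene_effects <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  r <- cfg$baseline_log_mean_range
  base <- runif(cfg$n_genes, r[1], r[2])
  module_idx <- sort(unique(unlist(cfg$gene_modules)))
  # Module genes are placed in the upper half of the abundance range so that
  # batch/biomarker/marker structure survives the coverage filter.
  base[module_idx] <- runif(length(module_idx), mean(r), r[2])
  case_effect <- numeric(cfg$n_genes)
  bio <- cfg$gene_modules$biomarker
  if (length(bio)) case_effect[bio] <- rnorm(length(bio), 0, cfg$case_effect_sd)
  structure(list(base = base, case_effect = case_effect,
                 hospital_effects = list(), n_genes = cfg$n_genes),
            class = "sim_effects")
}

new_hospital_effect <- function(cfg) {
  eff <- numeric(cfg$n_genes)
  mod <- cfg$gene_modules$platelet_activation
  if (length(mod)) eff[mod] <- rnorm(length(mod), 0, cfg$hospital_effect_sd)
  eff
}

#' Simulate a negative-binomial count matrix for a sample sheet
#'
#' @param meta Metadata from [build_confounded_design()] (columns
#'   `sample_id`, `group`, `hospital`, `age`).
#' @param cfg A [sim_config()].
#' @param seed RNG seed; identical seed (and effects) gives an identical
#'   matrix.
#' @param effects Optional [sim_gene_effects()] object; drawn from
#'   `cfg`/`seed` when omitted. Hospitals without a stored effect vector get
#'   a fresh one (recorded in the returned attribute).
#' @return Integer matrix genes x samples with gene/sample ids in dimnames.
#'   Attributes: `effects` (updated effects object), `contaminated`
#'   (character vector of spiked sample ids).
#' @export
simulate_counts <- function(meta, cfg, seed = cfg$seed, effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- check_meta(meta)
  if (nrow(meta) == 0) abort("Metadata is empty.")
  overlap <- intersect(cfg$gene_modules$platelet_activation, cfg$gene_modules$biomarker)
  if (length(overlap)) {
    abort("Batch and biomarker modules overlap; effects would not be identifiable.")
  }
  if (is.null(effects)) effects <- sim_gene_effects(cfg, seed)
  stopifnot(inherits(effects, "sim_effects"), effects$n_genes == cfg$n_genes)
  set.seed(seed + 1L)
  for (h in unique(meta$hospital)) {
    if (is.null(effects$hospital_effects[[h]])) {
      effects$hospital_effects[[h]] <- new_hospital_effect(cfg)
    }
  }
  n <- nrow(meta)
  g <- cfg$n_genes
  logmu <- matrix(effects$base, nrow = g, ncol = n)
  hosp_mat <- vapply(meta$hospital, function(h) effects$hospital_effects[[h]],
                     numeric(g))
  logmu <- logmu + hosp_mat
  is_case <- meta$group == "case"
  if (any(is_case)) logmu[, is_case] <- logmu[, is_case] + effects$case_effect
  rel <- 2^logmu
  contaminated <- character(0)
  if (cfg$contamination_rate > 0) {
    flags <- runif(n) < cfg$contamination_rate
    contaminated <- meta$sample_id[flags]
    markers <- unlist(cfg$gene_modules[c("haemoglobin_markers", "lymphocyte_markers")])
    if (length(markers) && any(flags)) {
      rel[markers, flags] <- rel[markers, flags] * cfg$contamination_strength
    }
  }
  depth <- rlnorm(n, log(cfg$depth_mean), cfg$libsize_log_sd)
  mu <- sweep(rel, 2, depth / colSums(rel), `*`)
  counts <- matrix(rnbinom(g * n, mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
                   nrow = g, ncol = n,
                   dimnames = list(sprintf("G%05d", seq_len(g)), meta$sample_id))
  attr(counts, "effects") <- effects
  attr(counts, "contaminated") <- contaminated
  counts
}

#' Write / read a count matrix as TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample.
#' @param counts Count matrix.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_counts(m)
}

#' Write / read sample metadata as TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @export
write_meta_tsv <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE,
                       colClasses = c(sample_id = "character")))
}
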