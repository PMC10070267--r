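#' Per-gene variance partitioning by a linear mixed model
#'
#' For every gene, fits `expr ~ age + (1 | hospital) + (1 | group)` by REML
#' and decomposes the expression variance into the hospital and
#' case-control variance components, the variance explained by the fixed
#' age term (variance of its fitted contribution) and the residual; the
#' four fractions sum to one. Genes with a singular (boundary) fit are
#' flagged but reported, since a zero variance component is itself the
#' boundary solution.
#'
#' @param expr Expression matrix (genes x samples), typically TMM-cpm-log2.
#' @param meta Metadata with `sample_id`, `group`, `hospital`, `age`
#'   aligned to the columns of `expr`.
#' @return A `tep_vp` tibble: `gene_id`, `fraction_hospital`,
#'   `fraction_cancer`, `fraction_age`, `fraction_residual`, `singular`.
#' @export
variance_partition <- function(expr, meta) {
  meta <- check_meta(meta)
  if (!identical(colnames(expr), meta$sample_id)) {
    abort("`expr` columns must match `meta$sample_id` in order.")
  }
  if (length(unique(meta$hospital)) < 2 || length(unique(meta$group)) < 2) {
    abort("Both random terms need at least two levels.")
  }
  df <- data.frame(age = meta$age, hospital = factor(meta$hospital),
                   cancer = factor(meta$group))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    df$y <- expr[i, ]
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ age + (1 | hospital) + (1 | cancer), data = df,
                 REML = TRUE, control = ctrl)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_hosp <- vc$vcov[vc$grp == "hospital"]
    v_cancer <- vc$vcov[vc$grp == "cancer"]
    v_resid <- vc$vcov[vc$grp == "Residual"]
    v_age <- var(lme4::fixef(fit)[["age"]] * df$age)
    total <- v_hosp + v_cancer + v_resid + v_age
    tibble(gene_id = rownames(expr)[i],
           fraction_hospital = v_hosp / total,
           fraction_cancer = v_cancer / total,
           fraction_age = v_age / total,
           fraction_residual = v_resid / total,
           singular = lme4::isSingular(fit))
  })
  class(out) <- c("tep_vp", class(out))
  out
}

#' Violin plot of variance-partition fractions
#'
#' @param vp A [variance_partition()] result.
#' @return A ggplot object.
#' @export
plot_variance_partition <- function(vp) {
  df <- tidyr::pivot_longer(as_tibble(vp),
                            dplyr::starts_with("fraction_"),
                            names_to = "component", values_to = "fraction",
                            names_prefix = "fraction_")
  df$component <- factor(df$component,
                         levels = c("hospital", "cancer", "age", "residual"))
  ggplot(df, aes(x = .data$component, y = .data$fraction, fill = .data$component)) +
    geom_violin(scale = "width", show.legend = FALSE) +
    labs(x = NULL, y = "Fraction of variance explained") +
    theme_minimal()
}

#' Negative-binomial GLM differential expression
#'
#' Gene-wise negative-binomial generalised linear models with TMM offsets
#' and quasi-likelihood F-tests, as implemented in edgeR. The default
#' design `~ age + group + hospital` tests the case-control contrast
#' adjusted for age and centre; `~ age + hospital` supports comparisons
#' between hospitals within cases only or controls only.
#'
#' @param counts Count matrix (genes x samples).
#' @param meta Metadata aligned to the columns.
#' @param design Model formula over metadata columns (`group`, `hospital`,
#'   `age`).
#' @param coef Name (or index) of the tested coefficient; defaults to the
#'   last design column.
#' @return Tibble `gene_id`, `log2fc`, `log_cpm`, `dispersion`, `statistic`,
#'   `p_value`, `fdr`.
#' @export
nb_glm_de <- function(counts, meta, design = ~ age + group + hospital,
                      coef = NULL) {
  check_counts(counts)
  meta <- check_meta(meta, counts)
  df <- as.data.frame(meta)
  df$group <- factor(df$group, levels = c("control", "case"))
  mm <- model.matrix(design, data = df)
  if (qr(mm)$rank < ncol(mm)) abort("Design matrix is not full rank.")
  if (is.null(coef)) coef <- colnames(mm)[ncol(mm)]
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  dge <- edgeR::estimateDisp(dge, mm)
  fit <- edgeR::glmQLFit(dge, mm)
  test <- edgeR::glmQLFTest(fit, coef = coef)
  tt <- edgeR::topTags(test, n = Inf, sort.by = "none")$table
  tibble(gene_id = rownames(tt),
         log2fc = tt$logFC, log_cpm = tt$logCPM,
         dispersion = dge$tagwise.dispersion,
         statistic = tt$F, p_value = tt$PValue, fdr = tt$FDR)
}

#' ComBat batch correction (intercept model)
#'
#' Empirical-Bayes location/scale adjustment per gene and batch with
#' parametric priors, applied to TMM-cpm-log2 expression. By default no
#' biological covariates are retained (intercept model). A single batch is
#' returned unchanged with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param batch Batch label per sample (e.g. hospital of origin).
#' @param covariates Optional model matrix of covariates to protect.
#' @return Corrected expression matrix of the same dimensions.
#' @export
combat_correct <- function(expr, batch, covariates = NULL) {
  batch <- as.factor(batch)
  if (length(batch) != ncol(expr)) abort("`batch` must align with samples.")
  if (nlevels(droplevels(batch)) < 2) {
    warn("Only one batch present; returning the input unchanged.")
    return(expr)
  }
  if (any(table(batch) < 2)) abort("Each batch needs at least 2 samples.")
  out <- sva::ComBat(dat = expr, batch = batch, mod = covariates,
                     par.prior = TRUE, prior.plots = FALSE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Over-representation test for a gene set
#'
#' Hypergeometric upper-tail probability of observing at least the realised
#' overlap between a selected gene list and a gene set, within a stated
#' universe.
#'
#' @param selected_genes Genes of interest (e.g. significant DE genes);
#'   must lie within `universe`.
#' @param gene_set The annotated set (e.g. a platelet-activation module).
#' @param universe All genes eligible for selection.
#' @return Tibble `overlap`, `expected`, `p_value`.
#' @export
ora_test <- function(selected_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("Empty universe.")
  selected_genes <- unique(selected_genes)
  gene_set <- intersect(unique(gene_set), universe)
  if (!all(selected_genes %in% universe)) {
    abort("`selected_genes` must be a subset of `universe`.")
  }
  n_u <- length(universe); n_set <- length(gene_set)
  n_sel <- length(selected_genes)
  k <- length(intersect(selected_genes, gene_set))
  p <- phyper(k - 1, n_set, n_u - n_set, n_sel, lower.tail = FALSE)
  tibble(overlap = k, expected = n_sel * n_set / n_u, p_value = p)
}

#' Marker-based contamination scores
#'
#' Mean normalised expression over each marker set, per sample; used to
#' screen platelet preparations for erythrocyte (haemoglobin genes) and
#' lymphocyte (e.g. CD3 subunit) contamination.
#'
#' @param expr Expression matrix (genes x samples).
#' @param marker_sets Named list of gene-id vectors.
#' @return Tibble `sample_id`, `marker_set`, `score`.
#' @export
contamination_scores <- function(expr, marker_sets) {
  if (!length(marker_sets)) abort("No marker sets supplied.")
  purrr::imap_dfr(marker_sets, function(genes, name) {
    if (!length(genes)) abort(sprintf("Marker set '%s' is empty.", name))
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) {
      abort(sprintf("Marker set '%s' has genes absent from the matrix.", name))
    }
    tibble(sample_id = colnames(expr), marker_set = name,
           score = unname(colMeans(expr[genes, , drop = FALSE])))
  })
}

#' Read gene sets in GMT format
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}
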