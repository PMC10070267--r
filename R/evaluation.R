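as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels <- as.character(labels)
  if (all(labels %in% c("case", "control"))) return(labels == "case")
  f <- factor(labels)
  if (nlevels(f) != 2) abort("Labels must have exactly two classes.")
  f == levels(f)[2]
}

#' Area under the ROC curve
#'
#' The Mann-Whitney U statistic normalised by the number of case-control
#' pairs; tied scores count one half.
#'
#' @param labels Case/control labels (cases are the positive class; for
#'   0/1 or logical input, 1/TRUE is positive).
#' @param scores Numeric classifier scores, higher = more case-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  pos <- as_binary_labels(labels)
  if (length(pos) != length(scores)) abort("labels and scores must align.")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 for cases, V01 for controls.
delong_placements <- function(pos_scores, neg_scores) {
  v10 <- vapply(pos_scores, function(x) {
    mean((x > neg_scores) + 0.5 * (x == neg_scores))
  }, numeric(1))
  v01 <- vapply(neg_scores, function(y) {
    mean((pos_scores > y) + 0.5 * (pos_scores == y))
  }, numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance from DeLong's placement values with a
#' normal-theory interval truncated to \[0, 1\]. With perfect separation the
#' placement variance is zero and the interval collapses to the point
#' estimate.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
delong_ci <- function(labels, scores, level = 0.95) {
  pos <- as_binary_labels(labels)
  x <- scores[pos]; y <- scores[!pos]
  if (length(x) < 2 || length(y) < 2) {
    abort("DeLong interval needs at least two members of each class.")
  }
  auc <- roc_auc(labels, scores)
  pl <- delong_placements(x, y)
  v <- var(pl$v10) / length(x) + var(pl$v01) / length(y)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       se = se)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Samples with `score >= threshold` are called cases. Returns the AUC with
#' its DeLong interval alongside the 2x2-table metrics; recall equals
#' sensitivity and F1 is the harmonic mean of precision and recall.
#'
#' @inheritParams roc_auc
#' @param threshold Probability threshold (default 0.5).
#' @param ci_level Confidence level for the DeLong interval.
#' @return One-row tibble of class `tep_metrics`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5, ci_level = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  pos <- as_binary_labels(labels)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else NA_real_
  ci <- if (sum(pos) >= 2 && sum(!pos) >= 2) delong_ci(labels, scores, ci_level) else
    list(auc = roc_auc(labels, scores), ci_low = NA_real_, ci_high = NA_real_)
  out <- tibble(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                sensitivity = sens, specificity = spec,
                precision = prec, recall = sens, f1 = f1,
                accuracy = (tp + tn) / length(pos),
                tp = tp, fn = fn, tn = tn, fp = fp,
                n_cases = sum(pos), n_controls = sum(!pos))
  class(out) <- c("tep_metrics", class(out))
  out
}

#' F1 score from precision and recall
#'
#' @param precision,recall Rates in \[0, 1\].
#' @return Harmonic mean of the two.
#' @export
f1_score <- function(precision, recall) 2 * precision * recall / (precision + recall)

#' Stage-stratified evaluation of classifier predictions
#'
#' Evaluates all-stage, early-stage and late-stage performance; each stage
#' group uses the cases of that group together with all controls.
#'
#' @param predictions Tibble with `sample_id`, `score`.
#' @param meta Metadata with `sample_id`, `group` and, for cases, `stage`.
#' @param stage_groups Named list of stage labels; `NULL` entry = all cases.
#' @param threshold,ci_level Passed to [confusion_metrics()].
#' @return Tibble with one metrics row per stage group.
#' @export
evaluate_predictions <- function(predictions, meta,
                                 stage_groups = list(all = NULL,
                                                     early = c("I", "II"),
                                                     late = c("III", "IV")),
                                 threshold = 0.5, ci_level = 0.95) {
  df <- dplyr::inner_join(as_tibble(predictions), as_tibble(meta), by = "sample_id")
  if (nrow(df) == 0) abort("No overlap between predictions and metadata.")
  purrr::imap_dfr(stage_groups, function(stages, name) {
    keep <- df$group == "control" |
      (if (is.null(stages)) TRUE else df$stage %in% stages)
    sub <- df[keep, ]
    if (!any(sub$group == "case")) return(tibble())
    dplyr::mutate(confusion_metrics(sub$group, sub$score, threshold, ci_level),
                  stage_group = name, .before = 1)
  })
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr` sorted for plotting.
#' @export
roc_points <- function(labels, scores) {
  pos <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred & !pos) / sum(!pos),
           tpr = sum(pred & pos) / sum(pos))
  })
}

#' ROC plot for one or more prediction sets
#'
#' @param pred_list Named list of lists with `labels` and `scores`.
#' @return A ggplot object.
#' @export
plot_roc <- function(pred_list) {
  df <- purrr::imap_dfr(pred_list, function(p, name) {
    dplyr::mutate(roc_points(p$labels, p$scores),
                  classifier = sprintf("%s (AUC %.2f)", name,
                                       roc_auc(p$labels, p$scores)))
  })
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, colour = .data$classifier)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(linewidth = 0.8) +
    labs(x = "False positive rate", y = "True positive rate", colour = NULL) +
    theme_minimal()
}
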