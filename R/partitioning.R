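#' Partition configuration
#'
#' @param fractions Named fractions for the training / evaluation /
#'   internal-validation subsets; must be positive and sum to 1. The default
#'   is the 40\%/30\%/30\% schema used for platelet classifier development.
#' @param seed RNG seed for the within-stage shuffles and control matching.
#' @return A `partition_config` list.
#' @export
partition_config <- function(fractions = c(training = 0.40, evaluation = 0.30,
                                           internal_validation = 0.30),
                             seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  if (is.null(names(fractions))) {
    names(fractions) <- c("training", "evaluation", "internal_validation")
  }
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "partition_config")
}

# Largest-remainder apportionment of n units over fractions; ties between
# equal remainders are broken by the order of `fractions` (training first).
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Stage-stratified allocation of cases to partitions
#'
#' Within each tumour stage, cases are shuffled (by `cfg$seed`) and
#' allocated to the training / evaluation / internal-validation subsets by
#' largest-remainder rounding of the configured fractions; remainder ties
#' are broken in partition order (training, then evaluation, then internal
#' validation). The union of the three subsets is exactly the input.
#'
#' @param case_ids Character vector of case sample ids.
#' @param stages Stage label per case (same length).
#' @param cfg A [partition_config()].
#' @return Tibble `sample_id`, `partition`.
#' @export
stratified_case_split <- function(case_ids, stages, cfg = partition_config()) {
  if (length(case_ids) == 0) abort("No cases to allocate.")
  if (length(stages) != length(case_ids)) abort("One stage label per case is required.")
  set.seed(cfg$seed)
  parts <- names(cfg$fractions)
  out <- purrr::map_dfr(split(case_ids, stages), function(ids) {
    ids <- sample(ids)
    sizes <- largest_remainder(length(ids), cfg$fractions)
    tibble(sample_id = ids, partition = rep(parts, sizes))
  })
  out[match(case_ids, out$sample_id), ]
}

#' Age-matched control selection
#'
#' For the training and evaluation partitions, controls are matched to the
#' cases by greedy nearest-age matching without replacement: the cases are
#' visited in an order randomised by `seed`, and each consumes the unused
#' control closest in age. All remaining controls are assigned to the
#' internal validation partition.
#'
#' @param control_ages Named numeric vector (names = control sample ids).
#' @param case_ages_by_partition Named list with numeric age vectors for
#'   `training` and `evaluation` cases.
#' @param seed RNG seed.
#' @return Tibble `sample_id`, `partition`, `matched_case_age` (NA for the
#'   internal-validation remainder).
#' @export
match_age_controls <- function(control_ages, case_ages_by_partition, seed = 1L) {
  if (is.null(names(control_ages))) {
    names(control_ages) <- sprintf("C%04d", seq_along(control_ages))
  }
  demand <- sum(lengths(case_ages_by_partition[c("training", "evaluation")]))
  if (length(control_ages) < demand) {
    abort("Fewer controls than training + evaluation cases to match.")
  }
  set.seed(seed)
  available <- control_ages
  rows <- list()
  for (part in c("training", "evaluation")) {
    ages <- case_ages_by_partition[[part]]
    if (is.null(ages) || !length(ages)) next
    for (a in sample(ages)) {
      pick <- which.min(abs(available - a))
      rows[[length(rows) + 1L]] <- tibble(sample_id = names(available)[pick],
                                          partition = part, matched_case_age = a)
      available <- available[-pick]
    }
  }
  matched <- dplyr::bind_rows(rows)
  remainder <- tibble(sample_id = names(available),
                      partition = "internal_validation",
                      matched_case_age = NA_real_)
  out <- dplyr::bind_rows(matched, remainder)
  out[match(names(control_ages), out$sample_id), ]
}

#' Assign every sample in a metadata table to a partition
#'
#' Cases are allocated by [stratified_case_split()]; controls by
#' [match_age_controls()].
#'
#' @param meta Metadata tibble with `sample_id`, `group`, `age` and (for
#'   cases) `stage`.
#' @param cfg A [partition_config()].
#' @return `meta` with a `partition` column added.
#' @export
partition_samples <- function(meta, cfg = partition_config()) {
  meta <- check_meta(meta)
  cases <- meta[meta$group == "case", ]
  controls <- meta[meta$group == "control", ]
  case_split <- stratified_case_split(cases$sample_id, cases$stage, cfg)
  case_part <- setNames(case_split$partition, case_split$sample_id)
  case_ages <- split(cases$age[match(names(case_part), cases$sample_id)], case_part)
  ctrl_split <- match_age_controls(setNames(controls$age, controls$sample_id),
                                   case_ages, seed = cfg$seed)
  part <- c(case_part, setNames(ctrl_split$partition, ctrl_split$sample_id))
  dplyr::mutate(meta, partition = unname(part[.data$sample_id]))
}
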