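# Validation metrics: genotype concordance (total vs opposite error),
# replicate phenotype concordance, red-hair confusion, reference-bias
# flagging and imputation variability.

check_gt_classes <- function(x, what) {
  bad <- setdiff(unique(x), GT_CLASSES)
  if (length(bad) > 0L) {
    stop(what, " contains unknown genotype class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Compare imputed/test genotype calls against truth
#'
#' Counts two error types over (sample, marker, replicate) comparisons: the
#' *total error* (any imputed diploid genotype differing from truth,
#' including an imputed `MISSING`) and the *opposite error* (homozygous for
#' the opposite allele: `HOMREF` vs `HOMALT` in either direction), the
#' latter being the failure mode that most severely distorts phenotype
#' probabilities. Truth `MISSING` entries are excluded from the denominator;
#' test entries with no matching truth record are reported in the
#' `"unmatched"` attribute and excluded.
#'
#' @param truth data frame with `sample_id`, `rsid`, `gt_class`.
#' @param test data frame with `sample_id`, `rsid`, `gt_class` and any
#'   replicate/grouping columns (e.g. `coverage`, `replicate`).
#' @param group_by character vector of `test` columns to summarise by.
#' @return Data frame with the grouping columns plus `n_compared`,
#'   `n_total_error`, `n_opposite_error`, `frac_total`, `frac_opposite`.
#' @export
compare_genotypes <- function(truth, test, group_by = character(0)) {
  stopifnot(all(c("sample_id", "rsid", "gt_class") %in% names(truth)),
            all(c("sample_id", "rsid", "gt_class") %in% names(test)),
            all(group_by %in% names(test)))
  check_gt_classes(truth$gt_class, "truth")
  check_gt_classes(test$gt_class, "test")
  truth_key <- paste(truth$sample_id, truth$rsid, sep = "\r")
  if (anyDuplicated(truth_key)) {
    stop("truth has duplicated (sample, rsid) records", call. = FALSE)
  }
  test_key <- paste(test$sample_id, test$rsid, sep = "\r")
  idx <- match(test_key, truth_key)
  unmatched <- test[is.na(idx), c("sample_id", "rsid"), drop = FALSE]
  keep <- !is.na(idx)
  test <- test[keep, , drop = FALSE]
  truth_gt <- truth$gt_class[idx[keep]]
  informative <- truth_gt != "MISSING"
  test <- test[informative, , drop = FALSE]
  truth_gt <- truth_gt[informative]

  total_err <- test$gt_class != truth_gt
  opposite_err <- (truth_gt == "HOMREF" & test$gt_class == "HOMALT") |
    (truth_gt == "HOMALT" & test$gt_class == "HOMREF")

  if (length(group_by) == 0L) {
    groups <- data.frame(row.names = seq_len(nrow(test)))
    key <- rep("all", nrow(test))
  } else {
    groups <- test[, group_by, drop = FALSE]
    key <- do.call(paste, c(groups, sep = "\r"))
  }
  uk <- unique(key)
  first <- match(uk, key)
  out <- if (length(group_by) == 0L) {
    data.frame(row.names = seq_along(uk))
  } else {
    groups[first, , drop = FALSE]
  }
  out$n_compared <- as.integer(tapply(rep(1L, length(key)), key, sum)[uk])
  out$n_total_error <- as.integer(tapply(as.integer(total_err), key, sum)[uk])
  out$n_opposite_error <- as.integer(tapply(as.integer(opposite_err), key, sum)[uk])
  out$frac_total <- out$n_total_error / out$n_compared
  out$frac_opposite <- out$n_opposite_error / out$n_compared
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Fraction of replicate phenotype calls exactly matching truth
#'
#' @param truth_pheno one phenotype call row (needs the `trait` column).
#' @param replicate_phenos data frame of replicate calls for the same
#'   sample.
#' @param trait `"eye"`, `"hair"` or `"skin"`.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the trait is
#'   unavailable/undefined in truth.
#' @export
exact_match_fraction <- function(truth_pheno, replicate_phenos,
                                 trait = c("eye", "hair", "skin")) {
  trait <- match.arg(trait)
  if (nrow(replicate_phenos) < 1L) stop("need at least one replicate", call. = FALSE)
  truth_cat <- truth_pheno[[trait]][1L]
  if (is.na(truth_cat) || truth_cat %in% c("unavailable", "undefined")) {
    warning("truth ", trait, " phenotype unavailable; fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(replicate_phenos[[trait]] == truth_cat)
}

#' Red-hair false positive and false negative rates
#'
#' Pools all (individual x replicate) comparisons: the false negative rate
#' is the fraction of truth-red comparisons classified non-red, the false
#' positive rate the fraction of truth-non-red comparisons classified red.
#'
#' @param truth_phenos data frame with `sample_id` and `hair` (one row per
#'   individual).
#' @param test_phenos data frame with `sample_id` and `hair`; replicates
#'   appear as repeated rows.
#' @return List with `fp_rate`, `fn_rate`, `n_red_comparisons`,
#'   `n_nonred_comparisons`. A zero denominator yields `NA` with a warning.
#' @export
red_hair_confusion <- function(truth_phenos, test_phenos) {
  stopifnot(all(c("sample_id", "hair") %in% names(truth_phenos)),
            all(c("sample_id", "hair") %in% names(test_phenos)))
  truth_red <- stats::setNames(truth_phenos$hair == "red", truth_phenos$sample_id)
  idx <- match(test_phenos$sample_id, names(truth_red))
  if (anyNA(idx)) stop("test sample(s) absent from truth", call. = FALSE)
  is_red_truth <- unname(truth_red[idx])
  called_red <- test_phenos$hair == "red"
  n_red <- sum(is_red_truth)
  n_nonred <- sum(!is_red_truth)
  fn <- if (n_red == 0L) {
    warning("no truth-red comparisons; FN rate undefined", call. = FALSE)
    NA_real_
  } else {
    sum(is_red_truth & !called_red) / n_red
  }
  fp <- if (n_nonred == 0L) {
    warning("no truth-non-red comparisons; FP rate undefined", call. = FALSE)
    NA_real_
  } else {
    sum(!is_red_truth & called_red) / n_nonred
  }
  list(fp_rate = fp, fn_rate = fn,
       n_red_comparisons = n_red, n_nonred_comparisons = n_nonred)
}

#' Flag sample/marker combinations with systematic (reference-bias-like) error
#'
#' A combination whose mean imputation error across the high-coverage levels
#' reaches `threshold` is flagged as a candidate for reference panel bias:
#' error that persists at high coverage cannot be explained by missing
#' genotype information. Also reports which fraction of all errors (over all
#' coverages) falls inside the flagged set.
#'
#' @param per_combo_errors data frame with `sample_id`, `rsid`, `coverage`,
#'   `error_frac` (mean error frequency of that combination at that
#'   coverage) and `n_errors` (error count, used for attribution).
#' @param high_coverages coverage labels treated as "high" (default
#'   `c("original", "2x", "1x")`).
#' @param threshold mean high-coverage error frequency at or above which a
#'   combination is flagged (default 0.15).
#' @return List: `flagged` (data frame `sample_id`, `rsid`, `mean_high_error`)
#'   and `attribution` (fraction of all errors inside the flagged set).
#'   Combinations missing a high-coverage level are skipped with a warning.
#' @export
flag_high_error_combinations <- function(per_combo_errors,
                                         high_coverages = c("original", "2x", "1x"),
                                         threshold = 0.15) {
  need <- c("sample_id", "rsid", "coverage", "error_frac", "n_errors")
  stopifnot(all(need %in% names(per_combo_errors)))
  df <- per_combo_errors
  combo <- paste(df$sample_id, df$rsid, sep = "\r")
  flagged <- character(0)
  mean_high <- numeric(0)
  skipped <- character(0)
  for (cb in unique(combo)) {
    sub <- df[combo == cb & df$coverage %in% high_coverages, , drop = FALSE]
    if (!setequal(sub$coverage, high_coverages)) {
      skipped <- c(skipped, cb)
      next
    }
    m <- mean(sub$error_frac)
    if (m >= threshold) {
      flagged <- c(flagged, cb)
      mean_high <- c(mean_high, m)
    }
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " combination(s) skipped: missing high-coverage level",
            call. = FALSE)
  }
  total_errors <- sum(df$n_errors)
  attribution <- if (total_errors == 0) 0 else {
    sum(df$n_errors[combo %in% flagged]) / total_errors
  }
  parts <- strsplit(flagged, "\r", fixed = TRUE)
  list(
    flagged = data.frame(
      sample_id = vapply(parts, `[`, "", 1L),
      rsid = vapply(parts, `[`, "", 2L),
      mean_high_error = mean_high,
      stringsAsFactors = FALSE),
    attribution = attribution
  )
}

#' Imputation variability per site
#'
#' Imputation is probabilistic: replicate runs on the same input can return
#' different genotypes. Variability is `1 -` the frequency of the modal
#' genotype among replicates, per (sample, marker).
#'
#' @param replicate_calls data frame with `sample_id`, `rsid`, `gt_class`
#'   over at least 2 replicates per combination.
#' @return Data frame `sample_id`, `rsid`, `n_replicates`,
#'   `minor_genotype_freq`.
#' @export
imputation_variability <- function(replicate_calls) {
  stopifnot(all(c("sample_id", "rsid", "gt_class") %in% names(replicate_calls)))
  check_gt_classes(replicate_calls$gt_class, "replicate calls")
  combo <- paste(replicate_calls$sample_id, replicate_calls$rsid, sep = "\r")
  uk <- unique(combo)
  res <- lapply(uk, function(cb) {
    g <- replicate_calls$gt_class[combo == cb]
    if (length(g) < 2L) stop("need >= 2 replicates per (sample, rsid)", call. = FALSE)
    1 - max(table(g)) / length(g)
  })
  parts <- strsplit(uk, "\r", fixed = TRUE)
  data.frame(sample_id = vapply(parts, `[`, "", 1L),
             rsid = vapply(parts, `[`, "", 2L),
             n_replicates = as.integer(tapply(rep(1L, length(combo)), combo, sum)[uk]),
             minor_genotype_freq = unlist(res),
             stringsAsFactors = FALSE)
}
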