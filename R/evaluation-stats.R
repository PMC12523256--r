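# Extraction and staging-classification metrics, Wilson intervals,
# Fisher's exact and Pearson chi-squared tests.
#
# Scoring conventions: a both-missing field-document pair counts as correct
# for accuracy but enters neither precision's denominator (non-missing
# predictions) nor recall's (non-missing truths). An x_code such as "pNx"
# is a recorded value and scores as non-missing. F1 is defined as 0 when
# precision + recall = 0; displayed values are half-up rounded to 3
# decimals, stored values are unrounded.

#' Half-up rounding (for display parity with reported tables)
#'
#' Base R's `round()` rounds half to even; tabulated clinical metrics are
#' conventionally half-up (2334/2400 = 0.9725 prints as 0.973).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         0, 2 * precision * recall / (precision + recall))
}

is_scored_value <- function(x) {
  !is_missing(x, c("not_mentioned", "dash"))
}

#' Field-extraction metrics per parameter
#'
#' Compares predicted records with ground-truth records over the 16
#' parameters using [values_match()] normalization. Per parameter over n
#' documents: accuracy = matches / n (both-missing agreement is a match);
#' precision = correct non-missing predictions / all non-missing
#' predictions; recall = correct non-missing predictions / all non-missing
#' truths. The `Overall (micro)` row pools all 16 x n field-document pairs.
#'
#' @param predictions,truths Lists of [pathology_record()]s covering the
#'   same `report_id` sets.
#' @return Data frame with columns `parameter`, `correct`, `accuracy`,
#'   `precision`, `recall`, `f1` (unrounded), last row `Overall (micro)`.
#' @export
evaluate_fields <- function(predictions, truths) {
  pred_ids <- vapply(predictions, `[[`, character(1), "report_id")
  truth_ids <- vapply(truths, `[[`, character(1), "report_id")
  if (!setequal(pred_ids, truth_ids) || anyDuplicated(truth_ids)) {
    stop("predictions and truths must cover the same report_id set",
         call. = FALSE)
  }
  predictions <- predictions[match(truth_ids, pred_ids)]
  n <- length(truths)
  rows <- lapply(PARAMETER_NAMES, function(p) {
    match_v <- logical(n); pred_present <- logical(n)
    truth_present <- logical(n)
    for (i in seq_len(n)) {
      pv <- record_field(predictions[[i]], p)
      tv <- record_field(truths[[i]], p)
      match_v[i] <- values_match(p, pv, tv)
      pred_present[i] <- is_scored_value(pv)
      truth_present[i] <- is_scored_value(tv)
    }
    correct_nonmissing <- sum(match_v & pred_present & truth_present)
    data.frame(parameter = p,
               correct = sum(match_v),
               n_pred = sum(pred_present),
               n_truth = sum(truth_present),
               tp = correct_nonmissing,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  micro <- data.frame(parameter = "Overall (micro)",
                      correct = sum(tab$correct), n_pred = sum(tab$n_pred),
                      n_truth = sum(tab$n_truth), tp = sum(tab$tp),
                      stringsAsFactors = FALSE)
  tab <- rbind(tab, micro)
  n_docs <- ifelse(tab$parameter == "Overall (micro)",
                   n * length(PARAMETER_NAMES), n)
  tab$accuracy <- tab$correct / n_docs
  tab$precision <- ifelse(tab$n_pred > 0, tab$tp / tab$n_pred, NA_real_)
  tab$recall <- ifelse(tab$n_truth > 0, tab$tp / tab$n_truth, NA_real_)
  tab$f1 <- f1_score(tab$precision, tab$recall)
  tab[, c("parameter", "correct", "accuracy", "precision", "recall", "f1")]
}

#' Staging-classification metrics with Unknown collapsing
#'
#' Every `"Unknown (Missing ...)"` label collapses to a unified `"Unknown"`
#' on both sides; one-vs-rest TP/FP/FN per class observed in truth or
#' prediction; the `Overall (macro)` row is the unweighted mean of the
#' unrounded per-class precision/recall/F1. Classes are ordered by stage
#' order with Unknown last.
#'
#' @param predicted,truth Lists of `staging_result`s (or character labels)
#'   over the same report sets, aligned or carrying `report_id`s.
#' @return Data frame `class`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` plus the macro row.
#' @export
evaluate_staging <- function(predicted, truth) {
  as_labels <- function(x) {
    if (is.character(x)) return(x)
    labs <- vapply(x, stage_label, character(1))
    ids <- vapply(x, function(r) r$report_id %||% NA_character_,
                  character(1))
    if (!anyNA(ids)) names(labs) <- ids
    labs
  }
  p <- as_labels(predicted)
  t <- as_labels(truth)
  if (length(p) != length(t)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(t))) {
    if (!setequal(names(p), names(t))) {
      stop("predicted and truth must cover the same report_id set",
           call. = FALSE)
    }
    p <- p[names(t)]
  }
  p <- collapse_unknown(p)
  t <- collapse_unknown(t)
  classes <- intersect(STAGE_LEVELS, union(t, p))
  rows <- lapply(classes, function(cl) {
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall,
               f1 = f1_score(precision, recall), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  macro <- data.frame(class = "Overall (macro)", tp = NA_integer_,
                      fp = NA_integer_, fn = NA_integer_,
                      precision = mean(tab$precision, na.rm = TRUE),
                      recall = mean(tab$recall, na.rm = TRUE),
                      f1 = mean(tab$f1, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  rbind(tab, macro)
}

#' Per-class metrics from TP/FP/FN counts
#'
#' Arithmetic reproduction of a classification table: per-class precision,
#' recall and F1 from counts, plus the macro row (unweighted means of the
#' unrounded per-class values).
#'
#' @param tp,fp,fn Integer vectors of equal length.
#' @param class Optional class labels.
#' @return Data frame as in [evaluate_staging()].
#' @export
staging_metrics_from_counts <- function(tp, fp, fn, class = NULL) {
  stopifnot(length(tp) == length(fp), length(tp) == length(fn))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  tab <- data.frame(class = class %||% as.character(seq_along(tp)),
                    tp = tp, fp = fp, fn = fn,
                    precision = precision, recall = recall,
                    f1 = f1_score(precision, recall),
                    stringsAsFactors = FALSE)
  macro <- data.frame(class = "Overall (macro)", tp = NA_integer_,
                      fp = NA_integer_, fn = NA_integer_,
                      precision = mean(precision, na.rm = TRUE),
                      recall = mean(recall, na.rm = TRUE),
                      f1 = mean(tab$f1, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  rbind(tab, macro)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return List of class `proportion_ci`: `x`, `n`, `level`, `estimate`,
#'   `lower`, `upper` (proportions in `[0,1]`).
#' @export
#' @examples
#' wilson_ci(35, 122) # lower 0.214, upper 0.373
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(list(x = x, n = n, level = level, estimate = p,
                 lower = max(0, center - half), upper = min(1, center + half)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %.0f%% CI %.3f-%.3f (Wilson)\n",
              x$x, x$n, x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

# two-sided 2x2 Fisher p: sum of hypergeometric probabilities of all tables
# (with fixed margins) no more likely than the observed one
fisher_2x2_enumeration <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher's exact test for an r x 2 contingency table
#'
#' 2x2 tables are evaluated by full hypergeometric enumeration (two-sided:
#' the sum of probabilities of tables no more likely than the observed).
#' Larger r x 2 tables use exact network enumeration while a bounded
#' estimate of the table state space stays below `1e6`; beyond that a
#' Monte-Carlo p-value with `1e5` replicates is computed (seed the RNG for
#' reproducibility) and its standard error reported.
#'
#' @param table Matrix of non-negative integer counts with 2 columns and
#'   r >= 2 rows.
#' @return List `p_value`, `method`, and `mc_se` (NA unless Monte Carlo).
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), nrow = 2, byrow = TRUE)) # p = 2/252
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  stopifnot(ncol(tab) == 2, nrow(tab) >= 2, all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty margin", call. = FALSE)
  }
  if (nrow(tab) == 2) {
    return(list(p_value = fisher_2x2_enumeration(tab),
                method = "exact enumeration (2x2)", mc_se = NA_real_))
  }
  # bound on the number of tables with these margins
  state_space <- prod(pmin(rowSums(tab), sum(tab[, 1])) + 1)
  if (state_space < 1e6) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    list(p_value = p, method = "exact network enumeration", mc_se = NA_real_)
  } else {
    B <- 1e5
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
    list(p_value = p, method = sprintf("Monte Carlo (B = %d)", B),
         mc_se = sqrt(p * (1 - p) / B))
  }
}

#' Pearson chi-squared test without continuity correction
#'
#' @param table Matrix of counts, at least 2 x 2.
#' @return List `statistic`, `df`, `p_value`.
#' @export
chi_squared <- function(table) {
  tab <- as.matrix(table)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
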