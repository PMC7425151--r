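LEVELS <- c("indication", "primary_indication")

#' Cross-tabulate algorithm output against gold-standard labels
#'
#' For one combination and one classification level, joins predictions and
#' gold labels 1:1 on `case_id` and counts true/false positives/negatives.
#' Only cases from the combination's surgeon panel are evaluated (the
#' validated setting). A prediction is positive at the `indication` level
#' when the combination matched step 1 (status `primary` or `secondary`),
#' and at the `primary_indication` level when its status is `primary`. A
#' gold label is positive when the combination is among the case's
#' indications (indication level) or is its primary indication.
#'
#' @param predictions A classification tibble from [classify_cohort()].
#' @param gold A gold-label tibble (see [read_gold()]).
#' @param combination `"SPS"`, `"HD"`, `"KOA"`, or `"HOA"`.
#' @param level `"indication"` or `"primary_indication"`.
#' @return A `confusion_counts` object: list with `tp`, `fp`, `fn`, `tn`,
#'   `level`, `combination`, `n` (evaluated cases).
#' @export
confusion <- function(predictions, gold, combination, level) {
  combination <- match.arg(combination, COMBINATIONS)
  level <- match.arg(level, LEVELS)
  orphans <- c(setdiff(predictions$case_id, gold$case_id),
               setdiff(gold$case_id, predictions$case_id))
  if (length(orphans)) {
    abort(sprintf("unmatched case_id(s): %s",
                  paste(sort(unique(orphans)), collapse = ", ")))
  }
  panel <- if (combination %in% c("SPS", "HD")) "spine" else "hip_knee"
  pred <- predictions[predictions$panel == panel, ]
  g <- gold[match(pred$case_id, gold$case_id), ]

  status <- pred[[paste0(tolower(combination), "_status")]]
  pred_pos <- if (level == "indication") {
    status %in% c("primary", "secondary")
  } else {
    status == "primary"
  }
  gold_pos <- if (level == "indication") {
    vapply(g$indications, function(ind) combination %in% ind, logical(1))
  } else {
    g$primary_indication == combination
  }
  confusion_from_counts(
    tp = sum(pred_pos & gold_pos), fp = sum(pred_pos & !gold_pos),
    fn = sum(!pred_pos & gold_pos), tn = sum(!pred_pos & !gold_pos),
    level = level, combination = combination)
}

#' Build confusion counts directly from integers
#'
#' Constructor used to reconstruct published two-by-two tables (e.g. from a
#' gold-positive denominator and a false-negative count) and feed them
#' through the same metric functions as live output.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @param level,combination Metadata labels (see [confusion()]).
#' @return A `confusion_counts` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn,
                                  level = "primary_indication",
                                  combination = "KOA") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be nonnegative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 level = level, combination = combination,
                 n = as.integer(tp + fp + fn + tn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion %s / %s> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$combination, x$level, x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Sensitivity with an exact Clopper-Pearson interval
#'
#' Sensitivity is the true-positive rate among gold positives,
#' `tp / (tp + fn)`.
#'
#' @param counts A `confusion_counts` object.
#' @param alpha Two-sided significance level for the interval.
#' @return A one-row tibble: `metric`, `combination`, `level`, `point`,
#'   `ci_low`, `ci_high`, `n` (denominator), `alpha`.
#' @export
sensitivity <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fn
  if (n < 1) abort("sensitivity undefined: no gold-positive cases")
  metric_estimate("sensitivity", counts$tp, n, alpha, counts)
}

#' Specificity with an exact Clopper-Pearson interval
#'
#' Specificity is the true-negative rate among gold negatives,
#' `tn / (tn + fp)`.
#'
#' @inheritParams sensitivity
#' @return A one-row tibble (see [sensitivity()]).
#' @export
specificity <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tn + counts$fp
  if (n < 1) abort("specificity undefined: no gold-negative cases")
  metric_estimate("specificity", counts$tn, n, alpha, counts)
}

metric_estimate <- function(metric, x, n, alpha, counts) {
  ci <- clopper_pearson(x, n, alpha)
  tibble(metric = metric,
         combination = counts$combination,
         level = counts$level,
         point = x / n,
         ci_low = ci[["lower"]],
         ci_high = ci[["upper"]],
         n = as.integer(n),
         alpha = alpha)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval obtained by inverting binomial tail probabilities:
#' the lower endpoint is the success probability under which observing `x`
#' or more successes has probability `alpha/2` (0 when `x = 0`), the upper
#' endpoint the probability under which observing `x` or fewer has
#' probability `alpha/2` (1 when `x = n`). Computed via the equivalent
#' beta-quantile formulation.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(37, 53)   # ~ (0.56, 0.82)
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n || alpha <= 0 || alpha >= 1) {
    abort("clopper_pearson: require 0 <= x <= n, n >= 1, 0 < alpha < 1")
  }
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Positive and negative predictive values at a given prior probability
#'
#' Bayes' rule applied to a binary test: with sensitivity `Se`, specificity
#' `Sp`, and prior (prevalence) `p`,
#' `PPV = Se*p / (Se*p + (1-Sp)*(1-p))` and
#' `NPV = Sp*(1-p) / (Sp*(1-p) + (1-Se)*p)`. A zero denominator (e.g. PPV
#' at `p = 0` with perfect specificity) yields `NaN` — the value is
#' undefined there, not zero.
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @param p Prior probability (vectorized) in \[0, 1\].
#' @return A tibble with columns `p`, `ppv`, `npv`.
#' @export
predictive_values <- function(se, sp, p) {
  if (any(c(se, sp, p) < 0) || any(c(se, sp, p) > 1)) {
    abort("predictive_values: se, sp, p must lie in [0, 1]")
  }
  ppv_den <- se * p + (1 - sp) * (1 - p)
  npv_den <- sp * (1 - p) + (1 - se) * p
  tibble(p = p,
         ppv = ifelse(ppv_den == 0, NaN, se * p / ppv_den),
         npv = ifelse(npv_den == 0, NaN, sp * (1 - p) / npv_den))
}

#' Predictive-value curve over a grid of prior probabilities
#'
#' @param se,sp Sensitivity and specificity in \[0, 1\].
#' @param grid Sorted vector of prior probabilities in \[0, 1\] (default
#'   101 equally spaced points).
#' @param combination Optional combination label carried into the output.
#' @param mark_priors Optional priors to annotate: evaluated and flagged in
#'   a logical `marked` column (appended grid points).
#' @return A tibble `combination`, `p`, `ppv`, `npv`, `marked`.
#' @export
pv_curve <- function(se, sp, grid = seq(0, 1, by = 0.01), combination = NA,
                     mark_priors = NULL) {
  if (is.unsorted(grid)) abort("pv_curve: grid must be sorted")
  base <- predictive_values(se, sp, grid)
  base$marked <- FALSE
  if (length(mark_priors)) {
    marks <- predictive_values(se, sp, mark_priors)
    marks$marked <- TRUE
    base <- dplyr::arrange(dplyr::bind_rows(base, marks), .data$p)
  }
  dplyr::bind_cols(tibble(combination = rep(combination, nrow(base))), base)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Unweighted kappa `(po - pe) / (1 - pe)` where `po` is the observed
#' agreement proportion (diagonal mass) and `pe` the agreement expected
#' from the raters' marginal distributions. Returns 1 under perfect
#' agreement; `NaN` (undefined) when chance agreement is 1.
#'
#' @param table A square contingency matrix of category counts, raters in
#'   rows/columns over the same cases.
#' @return Kappa as a single number.
#' @examples
#' cohens_kappa(matrix(c(45, 5, 5, 45), 2))  # 0.8
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    abort("cohens_kappa: contingency table must be square")
  }
  total <- sum(table)
  if (total <= 0) abort("cohens_kappa: table must have positive total")
  po <- sum(diag(table)) / total
  pe <- sum(rowSums(table) * colSums(table)) / total^2
  if (pe == 1) {
    warn("cohens_kappa: chance agreement is 1; kappa undefined")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Validate a classified cohort at both levels
#'
#' Convenience wrapper: computes confusion counts, sensitivity and
#' specificity for every combination at both classification levels.
#'
#' @param predictions A classification tibble from [classify_cohort()].
#' @param gold A gold-label tibble.
#' @param alpha Significance level for the Clopper-Pearson intervals.
#' @return A tibble with one row per combination x level x metric, plus
#'   `tp`, `fp`, `fn`, `tn` columns. A metric whose denominator is zero in
#'   this cohort (e.g. no gold-positive cases for a combination) is skipped
#'   with a message rather than reported as 0.
#' @export
validate_cohort <- function(predictions, gold, alpha = 0.05) {
  purrr::map_dfr(COMBINATIONS, function(combo) {
    purrr::map_dfr(LEVELS, function(lvl) {
      cc <- confusion(predictions, gold, combo, lvl)
      est <- purrr::map_dfr(list(sensitivity, specificity), function(f) {
        tryCatch(f(cc, alpha), error = function(e) {
          inform(sprintf("%s/%s: %s", combo, lvl, conditionMessage(e)))
          NULL
        })
      })
      if (nrow(est) == 0) return(NULL)
      est$tp <- cc$tp; est$fp <- cc$fp; est$fn <- cc$fn; est$tn <- cc$tn
      est
    })
  })
}

#' Audit misclassified cases for their mechanical cause
#'
#' Tags every false positive and false negative (at the primary-indication
#' level, per combination) with the cause recoverable from the claims data
#' alone: `exclusion_demotion:<pattern>` when an exclusion pattern demoted
#' a gold-primary case to secondary, `tie_break_override` when the spine
#' age tie-break swapped SpS and HD, `missing_cpt` / `missing_icd` when the
#' window lacked an inclusion code, and `unresolved` when the error has no
#' mechanical signature in the data (those require chart review).
#'
#' @param predictions A classification tibble from [classify_cohort()].
#' @param gold A gold-label tibble.
#' @return A tibble: `case_id`, `combination`, `error` (`"FP"`/`"FN"`),
#'   `cause`.
#' @export
misclassification_report <- function(predictions, gold) {
  purrr::map_dfr(COMBINATIONS, function(combo) {
    panel <- if (combo %in% c("SPS", "HD")) "spine" else "hip_knee"
    other_spine <- setdiff(c("SPS", "HD"), combo)
    pred <- predictions[predictions$panel == panel, ]
    g <- gold[match(pred$case_id, gold$case_id), ]
    status <- pred[[paste0(tolower(combo), "_status")]]
    cpt_hit <- pred[[paste0(tolower(combo), "_cpt_hit")]]
    icd_hit <- pred[[paste0(tolower(combo), "_icd_hit")]]
    pred_pos <- status == "primary"
    gold_pos <- g$primary_indication == combo

    fn_idx <- which(!pred_pos & gold_pos)
    fn <- purrr::map_dfr(fn_idx, function(i) {
      cause <- if (status[i] == "secondary") {
        hits <- pred$exclusion_hits[[i]]
        pats <- unique(hits$pattern[hits$combination == combo])
        paste0("exclusion_demotion:", paste(pats, collapse = ","))
      } else if (panel == "spine" && pred$tie_break_applied[i] &&
                 pred[[paste0(tolower(other_spine), "_status")]][i] !=
                   "not_indicated") {
        "tie_break_override"
      } else if (!cpt_hit[i]) {
        "missing_cpt"
      } else if (!icd_hit[i]) {
        "missing_icd"
      } else {
        "unresolved"
      }
      tibble(case_id = pred$case_id[i], combination = combo,
             error = "FN", cause = cause)
    })

    fp_idx <- which(pred_pos & !gold_pos)
    fp <- purrr::map_dfr(fp_idx, function(i) {
      cause <- if (panel == "spine" && pred$tie_break_applied[i] &&
                   g$primary_indication[i] == other_spine) {
        "tie_break_override"
      } else {
        "unresolved"
      }
      tibble(case_id = pred$case_id[i], combination = combo,
             error = "FP", cause = cause)
    })
    dplyr::bind_rows(fn, fp)
  })
}
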