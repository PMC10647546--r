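#' Misclassification penalty weights
#'
#' The cost-sensitive weighting of screening errors: missing a mild,
#' moderate or severe malnutrition case costs 1, 3 or 5 penalty units
#' respectively, and flagging a patient with no malnutrition costs 0.2 —
#' misses are weighted far above false alarms because the screen's purpose
#' is not to overlook malnutrition.
#'
#' @param miss_mild,miss_moderate,miss_severe Penalty per missed case of
#'   each severity (nonnegative).
#' @param false_positive Penalty per patient flagged without malnutrition.
#' @return Object of class `penalty_weights`.
#' @export
penalty_weights <- function(miss_mild = 1, miss_moderate = 3,
                            miss_severe = 5, false_positive = 0.2) {
  w <- c(miss_mild = miss_mild, miss_moderate = miss_moderate,
         miss_severe = miss_severe, false_positive = false_positive)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("penalty weights must be nonnegative and finite", call. = FALSE)
  }
  structure(as.list(w), class = "penalty_weights")
}

#' @export
print.penalty_weights <- function(x, ...) {
  cat(sprintf(
    "Penalty weights: miss mild %g, moderate %g, severe %g; false positive %g\n",
    x$miss_mild, x$miss_moderate, x$miss_severe, x$false_positive))
  invisible(x)
}

#' Weighted prediction quality score
#'
#' The penalty assigned to a set of screen predictions. Under
#' `"all_levels"`, every malnutrition grade counts as positive:
#' `score = w_mild * FN_mild + w_moderate * FN_moderate +
#' w_severe * FN_severe + w_fp * FP_none`. Under
#' `"moderate_severe_only"`, none and mild are grouped as the negative
#' class: missed moderate/severe cases keep their weights and every flagged
#' none-or-mild patient is charged the false-positive weight. Lower is
#' better; a perfect predictor scores 0.
#'
#' @param confusion A [severity_confusion()].
#' @param weights A [penalty_weights()].
#' @param mode `"all_levels"` or `"moderate_severe_only"`.
#' @return Nonnegative penalty score.
#' @examples
#' cm <- severity_confusion(c("none", "mild", "severe"), c(TRUE, FALSE, TRUE))
#' penalty_score(cm)  # one missed mild case + one flagged none
#' @export
penalty_score <- function(confusion, weights = penalty_weights(),
                          mode = c("all_levels", "moderate_severe_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(confusion, "severity_confusion"))
  if (any(confusion < 0)) stop("confusion counts must be nonnegative",
                               call. = FALSE)
  if (mode == "all_levels") {
    weights$miss_mild * confusion["neg", "mild"] +
      weights$miss_moderate * confusion["neg", "moderate"] +
      weights$miss_severe * confusion["neg", "severe"] +
      weights$false_positive * confusion["pos", "none"]
  } else {
    weights$miss_moderate * confusion["neg", "moderate"] +
      weights$miss_severe * confusion["neg", "severe"] +
      weights$false_positive *
        (confusion["pos", "none"] + confusion["pos", "mild"])
  }
}

#' Exhaustive best-subset selection over screen elements
#'
#' Scores every nonempty subset of the element vocabulary: a subset predicts
#' malnutrition by the screen's any-positive rule, the prediction is
#' cross-classified against severity, and the subset receives the weighted
#' penalty of its errors. Reports the minimum-penalty subset(s) at each size
#' and overall; ties are preserved, ordered lexicographically by element
#' names. Status-change elements are excluded from the default vocabulary
#' because they fire too rarely to inform selection; pass them in
#' `elements` to re-include them.
#'
#' @param cohort Assessed patient-level cohort (rows with unknown severity
#'   are dropped with a message).
#' @param elements Element vocabulary to search over (at most 20; the search
#'   enumerates all `2^K - 1` subsets).
#' @param weights A [penalty_weights()].
#' @param mode Malnutrition definition, as in [penalty_score()].
#' @return Object of class `selection_result`: list with `models` (every
#'   scored subset), `per_size_best`, `global_best`, `confusions` (one
#'   [severity_confusion()] per scored subset, for audit), `mode`,
#'   `weights`, `elements`.
#' @export
enumerate_models <- function(cohort, elements = cwnst_elements("daily"),
                             weights = penalty_weights(),
                             mode = c("all_levels", "moderate_severe_only")) {
  mode <- match.arg(mode)
  if (!length(elements)) stop("element vocabulary is empty", call. = FALSE)
  if (length(elements) > 20) {
    stop("exhaustive search is capped at 20 elements (2^K - 1 subsets); ",
         "reduce the vocabulary or use a greedy screen", call. = FALSE)
  }
  absent <- setdiff(elements, names(cohort))
  if (length(absent)) {
    stop("cohort lacks element column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  keep <- cohort$severity %in% severity_levels()
  if (!all(keep)) {
    message("dropping ", sum(!keep), " patient(s) with unknown severity")
    cohort <- cohort[keep, , drop = FALSE]
  }
  if (!nrow(cohort)) stop("no assessed patients to score", call. = FALSE)

  elements <- sort(elements)
  positive_class <- if (mode == "all_levels") "any_malnutrition"
                    else "moderate_severe"
  subsets <- unlist(
    lapply(seq_along(elements), function(k) {
      combos <- utils::combn(elements, k, simplify = FALSE)
      combos[order(vapply(combos, paste, "", collapse = "|"))]
    }),
    recursive = FALSE
  )
  confusions <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    cm <- severity_confusion(cohort$severity,
                             screen_positive(cohort, sub))
    met <- diagnostic_metrics(cm, positive_class)
    confusions[[i]] <- cm
    rows[[i]] <- data.frame(
      size = length(sub),
      score = penalty_score(cm, weights, mode),
      elements = paste(sub, collapse = ","),
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv,
      stringsAsFactors = FALSE
    )
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  names(confusions) <- models$elements

  size_f <- factor(models$size, levels = sort(unique(models$size)))
  per_size_best <- do.call(rbind, lapply(split(models, size_f), function(g) {
    g[g$score == min(g$score), , drop = FALSE]
  }))
  rownames(per_size_best) <- NULL
  global_best <- models[models$score == min(models$score), , drop = FALSE]
  rownames(global_best) <- NULL

  structure(
    list(models = models, per_size_best = per_size_best,
         global_best = global_best, confusions = confusions,
         mode = mode, weights = weights, elements = elements),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Best-subset screen selection (%s): %d subsets of %d elements scored\n",
    x$mode, nrow(x$models), length(x$elements)))
  cat("Best model(s) per size:\n")
  print(selection_report(x), row.names = FALSE)
  invisible(x)
}

#' Formatted best-model-per-size table
#'
#' Renders the per-size minimum-penalty models in the layout of the
#' published selection tables: subset size, penalty score to one decimal,
#' element labels, and the four diagnostic metrics to three decimals
#' (undefined metrics rendered `"undefined"`).
#'
#' @param result A [enumerate_models()] result.
#' @return Data frame with columns `N`, `Score`, `Screening Variables`,
#'   `Sensitivity`, `Specificity`, `PPV`, `NPV`; one row per (size, tied
#'   model).
#' @export
selection_report <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  best <- result$per_size_best
  fmt3 <- function(v) ifelse(is.na(v), "undefined", sprintf("%.3f", v))
  labels <- vapply(strsplit(best$elements, ",", fixed = TRUE), function(els) {
    paste(element_labels()[els], collapse = ", ")
  }, "")
  out <- data.frame(
    N = best$size,
    Score = sprintf("%.1f", best$score),
    `Screening Variables` = labels,
    Sensitivity = fmt3(best$sensitivity),
    Specificity = fmt3(best$specificity),
    PPV = fmt3(best$ppv),
    NPV = fmt3(best$npv),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
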