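#' Severity-stratified confusion counts
#'
#' Cross-classifies screen predictions by the four-level malnutrition
#' severity. The stored counts are never dichotomised: the positive-class
#' choice (any malnutrition, or moderate/severe only) is applied downstream
#' by [diagnostic_metrics()] and [penalty_score()].
#'
#' @param severity Severity per patient, restricted to
#'   none/mild/moderate/severe (assessed patients only).
#' @param predicted Logical (or 0/1) screen prediction per patient.
#' @return Object of class `severity_confusion`: a 2 x 4 integer matrix with
#'   rows `pos`/`neg` and severity columns.
#' @examples
#' severity_confusion(c("none", "none", "mild", "severe"),
#'                    c(FALSE, TRUE, TRUE, FALSE))
#' @export
severity_confusion <- function(severity, predicted) {
  if (length(severity) != length(predicted)) {
    stop("severity and predicted must be aligned 1:1", call. = FALSE)
  }
  severity <- as_severity(severity, with_unknown = TRUE)
  if (anyNA(severity) || any(severity == "unknown")) {
    stop("confusion counts require known severities (assessed patients only)",
         call. = FALSE)
  }
  severity <- factor(as.character(severity), levels = severity_levels())
  predicted <- as.logical(predicted)
  if (anyNA(predicted)) stop("predictions must not be missing", call. = FALSE)
  m <- rbind(
    pos = table(severity[predicted]),
    neg = table(severity[!predicted])
  )
  m <- matrix(as.integer(m), nrow = 2,
              dimnames = list(prediction = c("pos", "neg"),
                              severity = severity_levels()))
  structure(m, class = c("severity_confusion", class(m)))
}

#' @export
print.severity_confusion <- function(x, ...) {
  cat("Screen confusion by malnutrition severity\n")
  print(unclass(x))
  invisible(x)
}

# TP/FP/FN/TN under a positive-class dichotomy
dichotomize_confusion <- function(confusion, positive_class) {
  stopifnot(inherits(confusion, "severity_confusion"))
  positive <- switch(positive_class,
                     any_malnutrition = c("mild", "moderate", "severe"),
                     moderate_severe = c("moderate", "severe"),
                     stop("unknown positive_class: ", positive_class,
                          call. = FALSE))
  negative <- setdiff(severity_levels(), positive)
  c(tp = sum(confusion["pos", positive]),
    fn = sum(confusion["neg", positive]),
    fp = sum(confusion["pos", negative]),
    tn = sum(confusion["neg", negative]))
}

#' Diagnostic accuracy metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)` under the
#' chosen malnutrition dichotomy. A metric whose denominator is zero is
#' undefined and reported as `NA`, never coerced to 0 or 1.
#'
#' @param confusion A [severity_confusion()] object.
#' @param positive_class `"any_malnutrition"` (none vs any) or
#'   `"moderate_severe"` (none and mild grouped as negative).
#' @return Object of class `diagnostic_metrics`: named list with
#'   `sensitivity`, `specificity`, `ppv`, `npv` and the underlying
#'   `tp`/`fn`/`fp`/`tn` counts.
#' @examples
#' cm <- severity_confusion(rep(c("none", "mild"), c(3, 2)),
#'                          c(FALSE, FALSE, TRUE, TRUE, FALSE))
#' diagnostic_metrics(cm)
#' @export
diagnostic_metrics <- function(confusion,
                               positive_class = c("any_malnutrition",
                                                  "moderate_severe")) {
  positive_class <- match.arg(positive_class)
  k <- dichotomize_confusion(confusion, positive_class)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      sensitivity = ratio(k[["tp"]], k[["tp"]] + k[["fn"]]),
      specificity = ratio(k[["tn"]], k[["tn"]] + k[["fp"]]),
      ppv = ratio(k[["tp"]], k[["tp"]] + k[["fp"]]),
      npv = ratio(k[["tn"]], k[["tn"]] + k[["fn"]]),
      tp = k[["tp"]], fn = k[["fn"]], fp = k[["fp"]], tn = k[["tn"]],
      positive_class = positive_class
    ),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf(
    "Diagnostic metrics (%s): sensitivity %s, specificity %s, PPV %s, NPV %s\n",
    x$positive_class, fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
    fmt(x$npv)))
  cat(sprintf("  counts: TP %d  FN %d  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention: the sum of
#' hypergeometric probabilities, at the observed margins, of all tables no
#' more probable than the observed one (the convention of mainstream
#' statistical software).
#'
#' @param table 2x2 matrix of nonnegative counts, or the four counts
#'   `a, b, c, d` read row-wise.
#' @param a,b,c,d Alternative scalar-count interface.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(24, 45, 13, 168), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(table)) table <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(!is.finite(table)) || any(table < 0) || any(table != floor(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("table total must be positive", call. = FALSE)
  # degenerate margins carry no information; only one table is possible
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  min(stats::fisher.test(table)$p.value, 1)
}

#' Per-element contingency counts from a patient-level cohort
#'
#' Tabulates each screen element (and the any-positive-screen aggregate of
#' all elements) across the requested stratification, producing the same
#' counts shape the bundled fixtures use.
#'
#' @param cohort Cohort data frame with element columns and `severity` /
#'   `assessed` columns.
#' @param stratification `"no_vs_any"` (assessed patients, no vs any
#'   malnutrition) or `"assessed_vs_not"` (single column for the unassessed
#'   stratum).
#' @return Counts data frame: assessed shape (`element`, `n_total`,
#'   `pos_total`, `n_none`, `pos_none`, `n_any`, `pos_any`) or unassessed
#'   shape (`element`, `n`, `pos`).
#' @export
tabulate_elements <- function(cohort,
                              stratification = c("no_vs_any",
                                                 "assessed_vs_not")) {
  stratification <- match.arg(stratification)
  elements <- intersect(cwnst_elements(), names(cohort))
  any_pos <- as.integer(screen_positive(cohort, elements))
  if (stratification == "no_vs_any") {
    sub <- cohort[cohort$assessed, , drop = FALSE]
    any_pos <- any_pos[cohort$assessed]
    maln <- sub$severity %in% c("mild", "moderate", "severe")
    pos_of <- function(v) c(sum(v), sum(v[!maln]), sum(v[maln]))
    rows <- rbind(
      any_positive_screen = pos_of(any_pos),
      t(vapply(sub[, elements, drop = FALSE], pos_of, numeric(3)))
    )
    data.frame(
      element = c("any_positive_screen", elements),
      n_total = nrow(sub), pos_total = rows[, 1],
      n_none = sum(!maln), pos_none = rows[, 2],
      n_any = sum(maln), pos_any = rows[, 3],
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    sub <- cohort[!cohort$assessed, , drop = FALSE]
    any_pos <- any_pos[!cohort$assessed]
    data.frame(
      element = c("any_positive_screen", elements),
      n = nrow(sub),
      pos = c(sum(any_pos), vapply(sub[, elements, drop = FALSE], sum,
                                   numeric(1))),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
}

#' Render "count (percent)" at one-decimal rounding
#'
#' Matches the published rendering: one decimal place, with a zero count
#' special-cased as `"0 (0%)"` and an empty stratum as `"-- (undefined)"`.
#'
#' @param pos Positive count.
#' @param n Stratum total.
#' @return Character scalar (vectorised over `pos`/`n`).
#' @export
format_count_pct <- function(pos, n) {
  mapply(function(p, nn) {
    if (nn == 0) return("-- (undefined)")
    if (p == 0) return("0 (0%)")
    sprintf("%d (%.1f%%)", p, 100 * p / nn)
  }, pos, n, USE.NAMES = FALSE)
}

#' Formatted contingency row for one screen element
#'
#' One report row: per-stratum `count (percent)` strings plus the two-sided
#' Fisher p for the no-vs-any stratification.
#'
#' @param counts Counts data frame (assessed or unassessed shape, as from
#'   [tabulate_elements()] or the bundled fixtures).
#' @param element Element name (or `"any_positive_screen"`).
#' @return One-row data frame.
#' @export
element_table <- function(counts, element) {
  report <- contingency_report(counts)
  row <- report[report$element == element, , drop = FALSE]
  if (!nrow(row)) stop("element '", element, "' not in counts", call. = FALSE)
  row
}

#' Contingency report in the published table layout
#'
#' For the assessed stratification: one row per element with total,
#' no-malnutrition and any-malnutrition `count (percent)` columns and the
#' Fisher exact p-value (rendered `<0.001` / `>0.999` at the extremes, as in
#' the published tables). For the unassessed stratification: element and
#' total columns only.
#'
#' @param counts Counts data frame (assessed or unassessed shape).
#' @return Data frame, one row per element.
#' @examples
#' contingency_report(assessed_element_counts())
#' @export
contingency_report <- function(counts) {
  if (all(c("n_none", "pos_none", "n_any", "pos_any") %in% names(counts))) {
    p <- vapply(seq_len(nrow(counts)), function(i) {
      fisher_exact(fixture_2x2(counts, counts$element[i]))
    }, numeric(1))
    data.frame(
      element = counts$element,
      label = unname(element_labels()[counts$element]),
      total = format_count_pct(counts$pos_total, counts$n_total),
      no_malnutrition = format_count_pct(counts$pos_none, counts$n_none),
      any_malnutrition = format_count_pct(counts$pos_any, counts$n_any),
      p_value = format_p(p),
      stringsAsFactors = FALSE
    )
  } else if (all(c("n", "pos") %in% names(counts))) {
    data.frame(
      element = counts$element,
      label = unname(element_labels()[counts$element]),
      total = format_count_pct(counts$pos, counts$n),
      stringsAsFactors = FALSE
    )
  } else {
    stop("unrecognised counts shape", call. = FALSE)
  }
}

#' @noRd
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001",
         ifelse(p > 0.999, ">0.999", sprintf("%.3f", p)))
}
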