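#' Bundled contingency-count fixtures
#'
#' The package ships the published per-element contingency counts so that all
#' worked examples and reports run without patient-level data: positivity
#' counts for each screen element among the 250 assessed patients (stratified
#' by no vs any malnutrition), the same for the 918 never-assessed patients,
#' and the assessed severity distribution (181/27/24/18).
#'
#' @return `assessed_element_counts()`: data frame with columns `element`,
#'   `n_total`, `pos_total`, `n_none`, `pos_none`, `n_any`, `pos_any`.
#'   `unassessed_element_counts()`: columns `element`, `n`, `pos`.
#'   `assessed_severity_counts()`: columns `severity`, `n`.
#' @export
assessed_element_counts <- function() {
  read_counts_fixture(system.file("extdata", "assessed_element_counts.tsv",
                                  package = "nutriscreen", mustWork = TRUE))
}

#' @rdname assessed_element_counts
#' @export
unassessed_element_counts <- function() {
  utils::read.delim(system.file("extdata", "unassessed_element_counts.tsv",
                                package = "nutriscreen", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname assessed_element_counts
#' @export
assessed_severity_counts <- function() {
  utils::read.delim(system.file("extdata", "assessed_severity_counts.tsv",
                                package = "nutriscreen", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @noRd
read_counts_fixture <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "n_none", "pos_none", "n_any", "pos_any")
  if (!all(need %in% names(counts))) {
    stop("counts fixture must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts
}

#' Expand stratified element counts into per-element pseudo-cohorts
#'
#' Turns a table of per-element positive counts, stratified either by
#' malnutrition status (no vs any) or by assessment status, into one
#' patient-level pseudo-cohort per element whose 2x2 table reproduces the
#' input counts exactly. Only the per-element margins are reproduced; no
#' joint structure across elements is claimed, which is why each element gets
#' its own pseudo-cohort rather than one shared patient table.
#'
#' Malnourished patients in the assessed strata carry severity `"mild"` by
#' default: the counts condition on the no-vs-any dichotomy only, so the
#' grade split within the malnourished stratum is not identified by the
#' fixture. Unassessed pseudo-patients carry severity `"unknown"`.
#'
#' @param counts Data frame of counts. Assessed shape: columns `element`,
#'   `n_none`, `pos_none`, `n_any`, `pos_any`. Unassessed shape: columns
#'   `element`, `n`, `pos`.
#' @return Named list (by element) of data frames with columns `patient_id`,
#'   `assessed`, `severity`, `malnourished`, `value`.
#' @examples
#' pc <- expand_contingency_fixture(assessed_element_counts())
#' table(pc$pnst_positive$malnourished, pc$pnst_positive$value)
#' @export
expand_contingency_fixture <- function(counts) {
  stopifnot(is.data.frame(counts), "element" %in% names(counts))
  assessed_shape <- all(c("n_none", "pos_none", "n_any", "pos_any") %in%
                          names(counts))
  if (!assessed_shape && !all(c("n", "pos") %in% names(counts))) {
    stop("counts must be in assessed (n_none/pos_none/n_any/pos_any) or ",
         "unassessed (n/pos) shape", call. = FALSE)
  }
  num <- counts[setdiff(names(counts), "element")]
  if (any(unlist(num) < 0) || any(unlist(num) != floor(unlist(num)))) {
    stop("fixture counts must be nonnegative integers", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    if (assessed_shape) {
      if (row$pos_none > row$n_none || row$pos_any > row$n_any) {
        stop("fixture error for element '", row$element,
             "': positive count exceeds stratum total", call. = FALSE)
      }
      value <- c(rep(1L, row$pos_any), rep(0L, row$n_any - row$pos_any),
                 rep(1L, row$pos_none), rep(0L, row$n_none - row$pos_none))
      severity <- c(rep("mild", row$n_any), rep("none", row$n_none))
      assessed <- TRUE
    } else {
      if (row$pos > row$n) {
        stop("fixture error for element '", row$element,
             "': positive count exceeds stratum total", call. = FALSE)
      }
      value <- c(rep(1L, row$pos), rep(0L, row$n - row$pos))
      severity <- rep("unknown", row$n)
      assessed <- FALSE
    }
    data.frame(
      patient_id = sprintf("%s_%04d", row$element, seq_along(value)),
      assessed = assessed,
      severity = as_severity(severity),
      malnourished = severity %in% c("mild", "moderate", "severe"),
      value = value,
      stringsAsFactors = FALSE
    )
  })
  stats::setNames(out, counts$element)
}

#' Re-tabulate a pseudo-cohort into its 2x2 contingency table
#'
#' Inverse of [expand_contingency_fixture()] for a single element: rows are
#' the malnourished and non-malnourished strata, columns the positive and
#' negative element states.
#'
#' @param pseudo One element's pseudo-cohort (a data frame with columns
#'   `malnourished` and `value`).
#' @return 2x2 integer matrix with rows `any`/`none` and columns
#'   `positive`/`negative`.
#' @export
tabulate_pseudo_cohort <- function(pseudo) {
  stopifnot(all(c("malnourished", "value") %in% names(pseudo)))
  m <- matrix(
    c(sum(pseudo$malnourished & pseudo$value == 1),
      sum(pseudo$malnourished & pseudo$value == 0),
      sum(!pseudo$malnourished & pseudo$value == 1),
      sum(!pseudo$malnourished & pseudo$value == 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(stratum = c("any", "none"),
                    element = c("positive", "negative"))
  )
  storage.mode(m) <- "integer"
  m
}

#' 2x2 table straight from a fixture counts row
#' @noRd
fixture_2x2 <- function(counts, element) {
  row <- counts[counts$element == element, ]
  if (nrow(row) != 1L) stop("element '", element, "' not found in counts")
  matrix(
    c(row$pos_any, row$n_any - row$pos_any,
      row$pos_none, row$n_none - row$pos_none),
    nrow = 2, byrow = TRUE,
    dimnames = list(stratum = c("any", "none"),
                    element = c("positive", "negative"))
  )
}
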