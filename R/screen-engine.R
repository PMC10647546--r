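#' Growth-reference z-score by the LMS method
#'
#' Converts a measurement to a z-score against a Box-Cox growth reference
#' row: `z = ((value/M)^L - 1) / (L * S)` for `|L| > 1e-12`, and the
#' log-normal limit `z = log(value/M) / S` as `L -> 0`. `L` is the Box-Cox
#' power, `M` the reference median and `S` the coefficient of variation.
#' Reference rows are caller-supplied; no growth reference is bundled.
#'
#' @param value Positive measurement (same units as `M`).
#' @param L,M,S LMS parameters; `M > 0`, `S > 0`.
#' @return Numeric z-score (vectorised over `value`).
#' @examples
#' lms_z(16, L = -1.6, M = 16, S = 0.08)  # the median maps to 0
#' @export
lms_z <- function(value, L, M, S) {
  stopifnot(length(L) == 1, length(M) == 1, length(S) == 1)
  if (!is.finite(M) || M <= 0 || !is.finite(S) || S <= 0 || !is.finite(L)) {
    stop("LMS parameters require finite L, M > 0, S > 0", call. = FALSE)
  }
  if (any(!is.finite(value) | value <= 0)) {
    stop("measurement values must be positive and finite", call. = FALSE)
  }
  if (abs(L) > 1e-12) {
    ((value / M)^L - 1) / (L * S)
  } else {
    log(value / M) / S
  }
}

#' Which anthropometric reference applies at a given corrected age
#'
#' Weight-for-length is used below two years corrected age, BMI-for-age at
#' two years and above.
#'
#' @param corrected_age_years Nonnegative corrected age in years.
#' @return `"weight_for_length"` or `"bmi_for_age"` (vectorised).
#' @export
anthro_reference <- function(corrected_age_years) {
  stopifnot(all(is.finite(corrected_age_years) & corrected_age_years >= 0))
  ifelse(corrected_age_years < 2, "weight_for_length", "bmi_for_age")
}

#' Anthropometric screen element
#'
#' Flags a z-score strictly below -1. The same threshold applies on both
#' sides of the age-two dispatch boundary (weight-for-length below two years
#' corrected age, BMI-for-age at or above); the caller supplies whichever
#' z-score the dispatch selects.
#'
#' @param z_score Finite z-score (vectorised).
#' @return Logical: `TRUE` iff `z_score < -1`.
#' @examples
#' anthropometric_element(c(-1.5, -1, -0.2))
#' @export
anthropometric_element <- function(z_score) {
  if (any(!is.finite(z_score))) {
    stop("z_score must be finite; handle missing anthropometry upstream",
         call. = FALSE)
  }
  z_score < -1
}

#' Evaluate the seven daily screen elements
#'
#' The pure daily predicates the EMR generates each morning at 06:00:
#' active enteral nutrition, active parenteral nutrition, intubation, two or
#' more food allergies, the merged anthropometric flag (z < -1), the
#' RD-identified-risk flag, and the admission-time PNST result carried
#' forward. Missing anthropometry (`NA` z-score) yields a `FALSE` flag with
#' a warning rather than an error: a daily automated screen cannot halt on a
#' missing measurement.
#'
#' The food-allergy threshold is two or more allergies (the tool's stated
#' definition; see the methods vignette for the documented >2-vs-2+
#' labelling discrepancy in published summaries of the tool).
#'
#' @param inputs Data frame with one row per patient(-day) and columns
#'   `on_enteral_nutrition`, `on_parenteral_nutrition`, `intubated`
#'   (logical), `n_food_allergies` (count), `anthro_z` (z-score, `NA` if
#'   unmeasured), `rd_identified_risk`, `pnst_positive` (logical).
#' @return Data frame of integer 0/1 columns named as in
#'   `cwnst_elements("daily")`, one row per input row.
#' @examples
#' evaluate_daily(data.frame(on_enteral_nutrition = FALSE,
#'                           on_parenteral_nutrition = TRUE,
#'                           intubated = FALSE, n_food_allergies = 0,
#'                           anthro_z = -0.3, rd_identified_risk = FALSE,
#'                           pnst_positive = FALSE))
#' @export
evaluate_daily <- function(inputs) {
  need <- c("on_enteral_nutrition", "on_parenteral_nutrition", "intubated",
            "n_food_allergies", "anthro_z", "rd_identified_risk",
            "pnst_positive")
  missing_cols <- setdiff(need, names(inputs))
  if (length(missing_cols)) {
    stop("daily inputs missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  z <- inputs$anthro_z
  if (anyNA(z)) {
    warning(sum(is.na(z)),
            " patient(-day)s have missing anthropometry; flag set negative",
            call. = FALSE)
  }
  anthro <- !is.na(z) & z < -1
  out <- data.frame(
    enteral_nutrition    = as.integer(isTRUE_vec(inputs$on_enteral_nutrition)),
    food_allergies_2plus = as.integer(!is.na(inputs$n_food_allergies) &
                                        inputs$n_food_allergies >= 2),
    intubation           = as.integer(isTRUE_vec(inputs$intubated)),
    parenteral_nutrition = as.integer(isTRUE_vec(inputs$on_parenteral_nutrition)),
    rd_identified_risk   = as.integer(isTRUE_vec(inputs$rd_identified_risk)),
    pnst_positive        = as.integer(isTRUE_vec(inputs$pnst_positive)),
    anthropometric_flag  = as.integer(anthro)
  )
  out[, cwnst_elements("daily")]
}

# NA-safe elementwise truth: missing inputs never fire an element
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Evaluate the three status-change elements
#'
#' Assessed on scheduled status-change days: intake below 50% of estimated
#' needs, NPO (nil per os) status, and unintentional weight loss of at least
#' 5%, each sustained over three or more consecutive days ending at the most
#' recent day of history. The weight-loss baseline is the highest weight
#' recorded so far in the current admission, recomputed daily.
#'
#' @param intake_fraction Numeric vector, fraction of estimated needs taken
#'   per hospital day (day 1 first); `NA` days break a streak.
#' @param npo Logical vector per hospital day.
#' @param weight_kg Numeric weight per hospital day; `NA` days break the
#'   weight-loss streak.
#' @param day Hospital day of evaluation; history must cover days up to
#'   `day - 1` at least.
#' @param scheduled_days Optional integer vector of scheduled status-change
#'   days (from [status_change_days()]); if supplied and `day` is not in it,
#'   an error is raised, or a warning when `permissive = TRUE`.
#' @param permissive Downgrade the off-schedule error to a warning.
#' @return Named logical vector `intake_lt50_3d`, `npo_gt3d`,
#'   `weight_loss_ge5pct`.
#' @examples
#' evaluate_status_change(intake_fraction = c(0.4, 0.4, 0.4),
#'                        npo = c(FALSE, FALSE, FALSE),
#'                        weight_kg = c(10, 10, 10), day = 4)
#' @export
evaluate_status_change <- function(intake_fraction, npo, weight_kg, day,
                                   scheduled_days = NULL, permissive = FALSE) {
  stopifnot(length(day) == 1, day >= 1)
  if (!is.null(scheduled_days) && !(day %in% scheduled_days)) {
    msg <- sprintf("hospital day %d is not a scheduled status-change day", day)
    if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  intake <- intake_fraction[seq_len(min(day, length(intake_fraction)))]
  npo_h <- npo[seq_len(min(day, length(npo)))]
  w <- weight_kg[seq_len(min(day, length(weight_kg)))]

  intake_flag <- trailing_streak(!is.na(intake) & intake < 0.5) >= 3
  npo_flag <- trailing_streak(!is.na(npo_h) & npo_h) >= 3

  baseline <- cummax(ifelse(is.na(w), -Inf, w))
  loss <- !is.na(w) & baseline > 0 & (w - baseline) / baseline <= -0.05
  weight_flag <- trailing_streak(loss) >= 3

  c(intake_lt50_3d = unname(intake_flag),
    npo_gt3d = unname(npo_flag),
    weight_loss_ge5pct = unname(weight_flag))
}

# length of the run of TRUEs ending at the last position
trailing_streak <- function(x) {
  if (!length(x)) return(0L)
  r <- rev(x)
  first_false <- which(!r)
  if (!length(first_false)) length(x) else first_false[1] - 1L
}

#' Scheduled status-change evaluation days
#'
#' Status-change elements are assessed on hospital day 4 and every Monday,
#' Wednesday and Friday thereafter. Hospital day 1 is the admission date.
#'
#' @param admission_date Admission date (`Date` or coercible).
#' @param horizon Number of hospital days covered (>= 1).
#' @return Ascending integer vector of hospital days, deduplicated.
#' @examples
#' status_change_days(as.Date("2019-03-04"), horizon = 10)  # Monday admission
#' @export
status_change_days <- function(admission_date, horizon) {
  stopifnot(horizon >= 1)
  admission_date <- as.Date(admission_date)
  days <- seq_len(horizon)
  dates <- admission_date + (days - 1)
  mwf <- as.integer(format(dates, "%u")) %in% c(1L, 3L, 5L)
  sort(unique(c(if (horizon >= 4) 4L, days[days > 4 & mwf])))
}

#' Any-positive aggregation of screen elements
#'
#' The tool flags a patient when any element of the chosen subset is
#' positive (the screen's OR rule).
#'
#' @param cohort Data frame with 0/1 element columns (a cohort or a single
#'   patient row).
#' @param subset Nonempty character vector of element names drawn from
#'   [cwnst_elements()].
#' @return Logical vector, one entry per row of `cohort`.
#' @examples
#' screen_positive(data.frame(enteral_nutrition = 1, pnst_positive = 0),
#'                 subset = c("enteral_nutrition", "pnst_positive"))
#' @export
screen_positive <- function(cohort, subset = cwnst_elements("daily")) {
  if (!length(subset)) {
    stop("element subset must be nonempty", call. = FALSE)
  }
  unknown <- setdiff(subset, cwnst_elements())
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(subset, names(cohort))
  if (length(absent)) {
    stop("cohort lacks element column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(cohort[, subset, drop = FALSE])
  rowSums(m == 1) > 0
}
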