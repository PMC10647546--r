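#' Screen element vocabulary
#'
#' The CWNST evaluates seven daily elements (the admission-time PNST result
#' carried forward, plus six EMR-generated predicates, with the BMI-for-age
#' and weight-for-length z-score flags merged into a single anthropometric
#' element because they are mutually exclusive by age) and three
#' status-change elements assessed on hospital day 4 and every Monday,
#' Wednesday and Friday thereafter.
#'
#' @param which One of `"daily"`, `"status"`, or `"all"`.
#' @return Character vector of element names.
#' @examples
#' cwnst_elements("daily")
#' @export
cwnst_elements <- function(which = c("all", "daily", "status")) {
  which <- match.arg(which)
  daily <- c(
    "enteral_nutrition",
    "food_allergies_2plus",
    "intubation",
    "parenteral_nutrition",
    "rd_identified_risk",
    "pnst_positive",
    "anthropometric_flag"
  )
  status <- c("intake_lt50_3d", "npo_gt3d", "weight_loss_ge5pct")
  switch(which, daily = daily, status = status, all = c(daily, status))
}

#' Human-readable labels for screen elements, in report order
#' @noRd
element_labels <- function() {
  c(
    any_positive_screen  = "Any positive screen",
    enteral_nutrition    = "Enteral nutrition",
    food_allergies_2plus = "2+ food allergies",
    intubation           = "Intubation",
    parenteral_nutrition = "Parenteral nutrition",
    rd_identified_risk   = "RD-identified risk",
    pnst_positive        = "Positive PNST",
    anthropometric_flag  = "BMI-for-age or weight-for-length z-score",
    intake_lt50_3d       = "Intake < 50% for 3 days",
    npo_gt3d             = "NPO for 3+ days",
    weight_loss_ge5pct   = "Weight loss of 5%+"
  )
}

#' Malnutrition severity scale
#'
#' Four-level ordinal severity assigned by registered-dietitian assessment;
#' patients never assessed by an RD carry the sentinel `"unknown"`, which is
#' distinct from `"none"` (their true status is unobserved, not negative).
#'
#' @param with_unknown Include the `"unknown"` sentinel level.
#' @return Character vector of severity levels, ordered none < mild <
#'   moderate < severe.
#' @export
severity_levels <- function(with_unknown = FALSE) {
  lev <- c("none", "mild", "moderate", "severe")
  if (with_unknown) c(lev, "unknown") else lev
}

#' Coerce a severity vector to the canonical factor
#' @noRd
as_severity <- function(x, with_unknown = TRUE) {
  lev <- severity_levels(with_unknown)
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lev)
  if (any(bad)) {
    stop("unknown severity value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = lev)
}
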