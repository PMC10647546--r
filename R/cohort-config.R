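#' Configuration for the synthetic PICU cohort generator
#'
#' Parameters of the synthetic cohort: stratum sizes, the severity
#' distribution among RD-assessed patients, and per-element positivity rates
#' conditional on malnutrition status. The defaults reproduce the published
#' study conditions: a 250-patient assessed stratum with severity split
#' 181/27/24/18 (none/mild/moderate/severe), element rates conditional on the
#' no-vs-any malnutrition dichotomy calibrated to the assessed-cohort
#' contingency counts, and a 918-patient unassessed stratum with its own
#' marginal element rates (parenteral nutrition and RD-identified risk are
#' structurally zero there: both imply RD involvement).
#'
#' @param n_assessed Number of RD-assessed patients (> 0).
#' @param n_unassessed Number of never-assessed patients (>= 0).
#' @param severity_probs Named probability vector over
#'   `c("none", "mild", "moderate", "severe")`; must sum to 1.
#' @param element_rates Data frame with columns `element`, `rate_none`
#'   (positivity given no malnutrition) and `rate_malnourished` (positivity
#'   given any malnutrition), one row per element of [cwnst_elements()].
#' @param unassessed_element_rates Named numeric vector of positivity rates
#'   for the unassessed stratum, one entry per element.
#' @param dependence Latent-correlation parameter in `[0, 1)`. At 0 the
#'   elements are conditionally independent given status; above 0 all
#'   elements within a patient load on a shared standard-logistic factor
#'   (marginal rates are preserved by intercept recalibration).
#' @param seed Master integer seed; per-stream child seeds are derived from
#'   it by a fixed counter scheme (see [child_seed()]).
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$severity_probs
#' @export
cohort_config <- function(n_assessed = 250L,
                          n_unassessed = 918L,
                          severity_probs = c(none = 181, mild = 27,
                                             moderate = 24, severe = 18) / 250,
                          element_rates = default_element_rates(),
                          unassessed_element_rates = default_unassessed_rates(),
                          dependence = 0,
                          seed = 1L) {
  cfg <- structure(
    list(
      n_assessed = as.integer(n_assessed),
      n_unassessed = as.integer(n_unassessed),
      severity_probs = severity_probs,
      element_rates = element_rates,
      unassessed_element_rates = unassessed_element_rates,
      dependence = dependence,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' @noRd
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.na(cfg$n_assessed) || cfg$n_assessed <= 0L) {
    stop("n_assessed must be a positive integer", call. = FALSE)
  }
  if (is.na(cfg$n_unassessed) || cfg$n_unassessed < 0L) {
    stop("n_unassessed must be a nonnegative integer", call. = FALSE)
  }
  p <- cfg$severity_probs
  if (!setequal(names(p), severity_levels())) {
    stop("severity_probs must be named over ",
         paste(severity_levels(), collapse = "/"), call. = FALSE)
  }
  p <- p[severity_levels()]
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-12) {
    stop("severity_probs must lie in [0, 1] and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  cfg$severity_probs <- p
  er <- cfg$element_rates
  if (!is.data.frame(er) ||
      !all(c("element", "rate_none", "rate_malnourished") %in% names(er))) {
    stop("element_rates must have columns element, rate_none, rate_malnourished",
         call. = FALSE)
  }
  missing_el <- setdiff(cwnst_elements(), er$element)
  if (length(missing_el)) {
    stop("element_rates missing element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  rates <- c(er$rate_none, er$rate_malnourished, cfg$unassessed_element_rates)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 1)) {
    stop("all element rates must be probabilities in [0, 1]", call. = FALSE)
  }
  missing_un <- setdiff(cwnst_elements(), names(cfg$unassessed_element_rates))
  if (length(missing_un)) {
    stop("unassessed_element_rates missing element(s): ",
         paste(missing_un, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(cfg$dependence) || cfg$dependence < 0 || cfg$dependence >= 1) {
    stop("dependence must lie in [0, 1)", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  cfg
}

#' Default per-element positivity rates for the assessed stratum
#'
#' Conditional positivity probabilities given no malnutrition (denominator
#' 181) and given any malnutrition (denominator 69), taken from the study's
#' assessed-cohort contingency counts.
#'
#' @return Data frame with columns `element`, `rate_none`, `rate_malnourished`.
#' @export
default_element_rates <- function() {
  counts <- assessed_element_counts()
  rows <- counts[counts$element != "any_positive_screen", ]
  data.frame(
    element = rows$element,
    rate_none = rows$pos_none / rows$n_none,
    rate_malnourished = rows$pos_any / rows$n_any,
    stringsAsFactors = FALSE
  )
}

#' Default per-element positivity rates for the unassessed stratum
#'
#' @return Named numeric vector over [cwnst_elements()].
#' @export
default_unassessed_rates <- function() {
  counts <- unassessed_element_counts()
  rows <- counts[counts$element != "any_positive_screen", ]
  stats::setNames(rows$pos / rows$n, rows$element)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic PICU cohort configuration\n")
  cat(sprintf("  assessed: %d  unassessed: %d  seed: %d  dependence: %g\n",
              x$n_assessed, x$n_unassessed, x$seed, x$dependence))
  cat("  severity probabilities:",
      paste(sprintf("%s %.3f", names(x$severity_probs), x$severity_probs),
            collapse = ", "), "\n")
  cat(sprintf("  %d elements with status-conditional rates\n",
              nrow(x$element_rates)))
  invisible(x)
}

#' Read or write a cohort configuration as YAML or JSON
#'
#' The on-disk form holds the same fields as [cohort_config()]; element rate
#' tables are stored as named maps. Format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a validated `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  er <- raw$element_rates
  if (!is.data.frame(er)) {
    er <- data.frame(
      element = names(er),
      rate_none = vapply(er, function(r) r$rate_none, numeric(1)),
      rate_malnourished = vapply(er, function(r) r$rate_malnourished, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  cohort_config(
    n_assessed = raw$n_assessed,
    n_unassessed = raw$n_unassessed,
    severity_probs = unlist(raw$severity_probs),
    element_rates = er,
    unassessed_element_rates = unlist(raw$unassessed_element_rates),
    dependence = raw$dependence,
    seed = raw$seed
  )
}

#' @rdname read_cohort_config
#' @param config A `cohort_config` object.
#' @export
write_cohort_config <- function(config, path) {
  config <- validate_cohort_config(config)
  er <- config$element_rates
  out <- list(
    n_assessed = config$n_assessed,
    n_unassessed = config$n_unassessed,
    severity_probs = as.list(config$severity_probs),
    element_rates = stats::setNames(
      lapply(seq_len(nrow(er)), function(i) {
        list(rate_none = er$rate_none[i],
             rate_malnourished = er$rate_malnourished[i])
      }),
      er$element
    ),
    unassessed_element_rates = as.list(config$unassessed_element_rates),
    dependence = config$dependence,
    seed = config$seed
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    # full double precision so a round-tripped config regenerates the
    # identical cohort
    yaml::write_yaml(out, path, precision = 17)
  }
  invisible(path)
}
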