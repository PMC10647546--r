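#' Derive a per-stream child seed from the master seed
#'
#' Random draws are split into fixed, documented streams (1 severity,
#' 2 assessed ages, 3 assessed latent factors, 4 assessed elements,
#' 5 unassessed ages, 6 unassessed latent factors, 7 unassessed elements),
#' each seeded independently as
#' `(seed + stream * 1000003) mod 2147483647`. Adding or resizing one
#' stratum therefore never perturbs draws in another stream.
#'
#' @param seed Master integer seed.
#' @param stream Positive integer stream counter.
#' @return Integer child seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + as.numeric(stream) * 1000003) %% 2147483647)
}

# Latent-factor loading from the dependence parameter: with a shared
# standard-logistic factor z and logistic threshold noise, the share of
# latent-scale variance carried by z is lambda^2 / (1 + lambda^2) = d.
dependence_loading <- function(dependence) {
  sqrt(dependence / (1 - dependence))
}

#' Intercept calibration under the shared latent factor
#'
#' Solves `E_z[plogis(a + lambda * z)] = p` for `a`, with `z` standard
#' logistic, so that configured marginal rates are preserved exactly (up to
#' quadrature tolerance) at any dependence level.
#' @noRd
calibrate_intercept <- function(p, lambda) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (lambda == 0) return(stats::qlogis(p))
  marginal <- function(a) {
    stats::integrate(function(z) stats::plogis(a + lambda * z) * stats::dlogis(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(marginal, c(-60, 60), tol = 1e-10)$root
}

# Lognormal ages truncated to [floor, 17] years by resampling; parameters
# are matched to the study's per-stratum median and mean.
draw_ages <- function(n, meanlog, sdlog, floor_age) {
  ages <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:50) {
    over <- ages > 17
    if (!any(over)) break
    ages[over] <- stats::rlnorm(sum(over), meanlog, sdlog)
  }
  pmax(pmin(ages, 17), floor_age)
}

#' Generate a synthetic PICU cohort
#'
#' Draws one patient-level cohort with the statistical structure the
#' screening evaluation assumes. Severity is drawn first from the assessed
#' severity distribution; each screen element is then drawn conditional on
#' the no-vs-any malnutrition dichotomy (the published conditional rates
#' condition on that dichotomy, not on the severity grade). Unassessed
#' patients carry severity `"unknown"` and their own marginal element rates,
#' with parenteral nutrition and RD-identified risk structurally zero by
#' default. When `dependence > 0`, all elements of one patient share a
#' standard-logistic latent factor added to each element's log-odds, with
#' marginal rates preserved by intercept recalibration.
#'
#' Identical `config` (including seed) yields a bitwise-identical cohort.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per patient: `patient_id`, `assessed`,
#'   `severity` (factor over none/mild/moderate/severe/unknown), `age_years`,
#'   `corrected_age_years`, and one integer 0/1 column per element of
#'   [cwnst_elements()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n_assessed = 50, n_unassessed = 0,
#'                                         seed = 42))
#' table(cohort$severity)
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  elements <- cwnst_elements()
  lambda <- dependence_loading(config$dependence)

  # --- assessed stratum ---
  n_a <- config$n_assessed
  set.seed(child_seed(config$seed, 1))
  severity <- sample(severity_levels(), n_a, replace = TRUE,
                     prob = config$severity_probs)

  set.seed(child_seed(config$seed, 2))
  age_a <- draw_ages(n_a, meanlog = log(2), sdlog = 1.31, floor_age = 0.01)
  premature <- stats::runif(n_a) < 0.10 & age_a < 2
  correction <- ifelse(premature, stats::runif(n_a, 0, 0.25), 0)
  corrected_a <- pmax(age_a - correction, 0)

  set.seed(child_seed(config$seed, 3))
  z_a <- if (lambda > 0) stats::rlogis(n_a) else numeric(n_a)

  malnourished <- severity != "none"
  er <- config$element_rates
  set.seed(child_seed(config$seed, 4))
  elem_a <- sapply(elements, function(el) {
    row <- er[er$element == el, ]
    a0 <- calibrate_intercept(row$rate_none, lambda)
    a1 <- calibrate_intercept(row$rate_malnourished, lambda)
    p <- stats::plogis(ifelse(malnourished, a1, a0) + lambda * z_a)
    as.integer(stats::runif(n_a) < p)
  })
  elem_a <- matrix(elem_a, nrow = n_a, dimnames = list(NULL, elements))

  assessed <- data.frame(
    patient_id = sprintf("A%05d", seq_len(n_a)),
    assessed = TRUE,
    severity = severity,
    age_years = age_a,
    corrected_age_years = corrected_a,
    stringsAsFactors = FALSE
  )
  assessed <- cbind(assessed, as.data.frame(elem_a))

  # --- unassessed stratum ---
  if (config$n_unassessed > 0) {
    n_u <- config$n_unassessed
    set.seed(child_seed(config$seed, 5))
    age_u <- draw_ages(n_u, meanlog = log(4), sdlog = 0.974, floor_age = 0.03)
    premature_u <- stats::runif(n_u) < 0.10 & age_u < 2
    correction_u <- ifelse(premature_u, stats::runif(n_u, 0, 0.25), 0)
    set.seed(child_seed(config$seed, 6))
    z_u <- if (lambda > 0) stats::rlogis(n_u) else numeric(n_u)
    set.seed(child_seed(config$seed, 7))
    elem_u <- sapply(elements, function(el) {
      a0 <- calibrate_intercept(config$unassessed_element_rates[[el]], lambda)
      p <- stats::plogis(a0 + lambda * z_u)
      as.integer(stats::runif(n_u) < p)
    })
    elem_u <- matrix(elem_u, nrow = n_u, dimnames = list(NULL, elements))
    unassessed <- data.frame(
      patient_id = sprintf("U%05d", seq_len(n_u)),
      assessed = FALSE,
      severity = "unknown",
      age_years = age_u,
      corrected_age_years = pmax(age_u - correction_u, 0),
      stringsAsFactors = FALSE
    )
    unassessed <- cbind(unassessed, as.data.frame(elem_u))
    cohort <- rbind(assessed, unassessed)
  } else {
    cohort <- assessed
  }

  cohort$severity <- as_severity(cohort$severity)
  rownames(cohort) <- NULL
  cohort
}

#' Read or write a patient-level cohort as delimited text
#'
#' One row per patient, header row, one 0/1 column per screen element, and a
#' `severity` column restricted to the controlled vocabulary
#' none/mild/moderate/severe/unknown. The delimiter follows the file
#' extension (`.csv` comma, otherwise tab).
#'
#' @param cohort Cohort data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- cohort
  out$severity <- as.character(out$severity)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cohort <- utils::read.table(path, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE)
  if (!"severity" %in% names(cohort)) {
    stop("cohort file must have a 'severity' column", call. = FALSE)
  }
  cohort$severity <- as_severity(cohort$severity)
  if (!"assessed" %in% names(cohort)) {
    cohort$assessed <- cohort$severity != "unknown"
  }
  cohort$assessed <- as.logical(cohort$assessed)
  present <- intersect(cwnst_elements(), names(cohort))
  if (!length(present)) {
    stop("cohort file contains no recognised screen element columns",
         call. = FALSE)
  }
  for (el in present) {
    v <- cohort[[el]]
    if (!all(v %in% c(0L, 1L))) {
      stop("element column '", el, "' must be binary 0/1", call. = FALSE)
    }
    cohort[[el]] <- as.integer(v)
  }
  cohort
}
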