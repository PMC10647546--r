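#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: where the cohort comes from
#' (the synthetic generator, a patient-level file, or the bundled
#' contingency-count fixtures), the penalty weights, which malnutrition
#' definitions to run the subset selection under, and where to write the
#' report bundle.
#'
#' @param cohort_source `"synthetic"`, `"file"` or `"fixture"`.
#' @param cohort_config A [cohort_config()] (synthetic source).
#' @param cohort_file Path to a patient-level cohort file (file source).
#' @param weights A [penalty_weights()].
#' @param modes Subset of `c("all_levels", "moderate_severe_only")`.
#' @param output_dir Directory for the report bundle (created if absent).
#' @param seed Optional integer overriding the cohort config's seed.
#' @param log_level `"info"`, `"warn"` or `"quiet"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_source = c("synthetic", "file", "fixture"),
                            cohort_config = nutriscreen::cohort_config(),
                            cohort_file = NULL,
                            weights = penalty_weights(),
                            modes = c("all_levels", "moderate_severe_only"),
                            output_dir = tempfile("nutriscreen_run_"),
                            seed = NULL,
                            log_level = c("info", "warn", "quiet")) {
  cohort_source <- match.arg(cohort_source)
  log_level <- match.arg(log_level)
  modes <- match.arg(modes, several.ok = TRUE)
  if (cohort_source == "file" &&
      (is.null(cohort_file) || !file.exists(cohort_file))) {
    stop("cohort_file: no readable cohort file supplied", call. = FALSE)
  }
  if (!is.null(seed)) cohort_config$seed <- as.integer(seed)
  structure(
    list(cohort_source = cohort_source, cohort_config = cohort_config,
         cohort_file = cohort_file, weights = weights, modes = modes,
         output_dir = output_dir, log_level = log_level),
    class = "pipeline_config"
  )
}

#' @noRd
pipe_log <- function(config, level, ...) {
  rank <- c(quiet = 0, warn = 1, info = 2)
  if (rank[[config$log_level]] >= rank[[level]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

#' Run the full screening-evaluation pipeline
#'
#' Obtains a cohort per the configuration, writes the patient-level snapshot
#' (when one exists), the stratified contingency reports, a best-subset
#' selection report per requested malnutrition definition with a full
#' audit record of every scored subset, a full-screen-vs-PNST comparison,
#' a machine-readable summary, and a manifest with content hashes. Identical
#' configuration (including seed) produces an identical bundle.
#'
#' With the fixture source, only the per-element margins are available, so
#' the contingency reports are produced and the joint-data stages (subset
#' selection, severity-specific comparison) are skipped with a log note.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort` or
#'   `counts`, `reports`, `selection`, `comparison`, `summary`, `manifest`)
#'   and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir)) {
    stop("output_dir is not writable: ", config$output_dir, call. = FALSE)
  }
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    paths[[name]] <<- path
    path
  }
  summary <- list(cohort_source = config$cohort_source)

  cohort <- NULL
  if (config$cohort_source == "synthetic") {
    pipe_log(config, "info", "generating synthetic cohort (seed ",
             config$cohort_config$seed, ")")
    cohort <- generate_cohort(config$cohort_config)
    summary$seed <- config$cohort_config$seed
  } else if (config$cohort_source == "file") {
    pipe_log(config, "info", "reading cohort from ", config$cohort_file)
    cohort <- read_cohort(config$cohort_file)
  }

  if (!is.null(cohort)) {
    emit("cohort.csv", function(p) write_cohort(cohort, p))
    assessed_counts <- tabulate_elements(cohort, "no_vs_any")
    unassessed_counts <- if (any(!cohort$assessed)) {
      tabulate_elements(cohort, "assessed_vs_not")
    }
    sev <- table(factor(as.character(
      cohort$severity[cohort$assessed]), levels = severity_levels()))
    summary$severity_counts <- as.list(sev)
  } else {
    pipe_log(config, "info", "using bundled contingency-count fixtures")
    assessed_counts <- assessed_element_counts()
    unassessed_counts <- unassessed_element_counts()
    sev <- assessed_severity_counts()
    summary$severity_counts <- as.list(stats::setNames(sev$n, sev$severity))
  }
  summary$assessed_counts <- assessed_counts
  report_assessed <- contingency_report(assessed_counts)
  emit("table_assessed_elements.tsv", function(p) {
    utils::write.table(report_assessed, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  reports <- list(assessed = report_assessed)
  if (!is.null(unassessed_counts)) {
    summary$unassessed_counts <- unassessed_counts
    reports$unassessed <- contingency_report(unassessed_counts)
    emit("table_unassessed_elements.tsv", function(p) {
      utils::write.table(reports$unassessed, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    })
  }

  selection <- list()
  comparison <- NULL
  if (!is.null(cohort)) {
    assessed <- cohort[cohort$assessed, , drop = FALSE]
    for (mode in config$modes) {
      pipe_log(config, "info", "best-subset selection, mode ", mode)
      res <- enumerate_models(assessed, weights = config$weights, mode = mode)
      selection[[mode]] <- res
      emit(paste0("selection_", mode, ".tsv"), function(p) {
        utils::write.table(selection_report(res), p, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      })
      emit(paste0("selection_", mode, "_all_subsets.json"), function(p) {
        jsonlite::write_json(res$models, p, digits = NA)
      })
      summary$selection[[mode]] <- list(
        per_size_best = res$per_size_best,
        global_best = res$global_best
      )
    }
    comparison <- comparison_table(assessed)
    emit("pnst_comparison.tsv", function(p) {
      utils::write.table(comparison, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    })
    summary$comparison <- comparison
  } else {
    pipe_log(config, "warn",
             "fixture source carries per-element margins only; ",
             "subset selection and severity-specific comparison skipped")
  }

  emit("summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  })
  manifest <- list(
    package = "nutriscreen",
    cohort_source = config$cohort_source,
    seed = if (config$cohort_source == "synthetic")
      config$cohort_config$seed,
    modes = config$modes,
    weights = unclass(config$weights),
    files = as.list(unname(tools::md5sum(unlist(paths))))
  )
  names(manifest$files) <- names(paths)
  emit("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  })
  pipe_log(config, "info", "bundle written to ", config$output_dir)

  invisible(list(cohort = cohort, counts = assessed_counts,
                 reports = reports, selection = selection,
                 comparison = comparison, summary = summary,
                 manifest = manifest, paths = paths))
}

#' Full-screen vs PNST-alone accuracy comparison
#'
#' Computes sensitivity, specificity, PPV and NPV of the whole daily screen
#' (any-positive over all seven daily elements) and of the PNST element
#' alone, under both malnutrition definitions, from a patient-level assessed
#' cohort.
#'
#' @param assessed Assessed patient-level cohort.
#' @return Data frame with one row per tool x malnutrition definition.
#' @export
comparison_table <- function(assessed) {
  tools <- list(
    "Full daily screen" = cwnst_elements("daily"),
    "PNST alone" = "pnst_positive"
  )
  defs <- c(any_malnutrition = "All levels of malnutrition",
            moderate_severe = "Moderate or severe malnutrition")
  rows <- list()
  for (tool in names(tools)) {
    pred <- screen_positive(assessed, tools[[tool]])
    cm <- severity_confusion(assessed$severity, pred)
    for (def in names(defs)) {
      met <- diagnostic_metrics(cm, def)
      rows[[length(rows) + 1L]] <- data.frame(
        tool = tool, definition = defs[[def]],
        sensitivity = met$sensitivity, specificity = met$specificity,
        ppv = met$ppv, npv = met$npv, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
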