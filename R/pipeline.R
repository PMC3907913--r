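#' Run the full diagnostic pipeline
#'
#' Chains the stages: annotation against the design, three-rule artifact
#' filtering, cohort indexing, whitelist-aware prioritization, and (when
#' evidence is supplied) rule-table classification of the candidates. The
#' run is deterministic: the same inputs and configuration reproduce the
#' same report.
#'
#' @param design a `panel_design`.
#' @param calls validated call data frame covering one or more patients
#'   (`patient_id` column required), or a list of per-patient tables.
#' @param whitelist optional known-pathogenic table ([read_whitelist()] or
#'   the simulator's).
#' @param cohort `"rebuild"` (default) to build the masking index from
#'   `calls` after artifact filtering, or a frozen `cohort_index`.
#' @param config a [panelsift_config()] or `NULL` for defaults.
#' @param profiles optional list of `coverage_profile` for the coverage
#'   section of the report.
#' @param evidence optional data frame of evidence vectors keyed by `key`
#'   for candidate classification.
#' @param rules `class_rules` used when `evidence` is given.
#' @param seed echoed into the report (the pipeline itself draws no random
#'   numbers).
#' @return list of class `panel_run_report`.
#' @export
run_pipeline <- function(design, calls, whitelist = NULL,
                         cohort = "rebuild", config = NULL,
                         profiles = NULL, evidence = NULL,
                         rules = default_rules(), seed = NULL) {
  config <- as_panelsift_config(config)
  if (!is.data.frame(calls)) calls <- do.call(rbind, calls)
  if (is.null(calls$patient_id) || anyNA(calls$patient_id))
    stop("calls must carry patient_id")
  if (is.null(calls$vtype)) calls$vtype <- infer_vtype(calls$ref, calls$alt)

  av <- annotate_calls(calls, design, whitelist = whitelist)
  flt <- apply_artifact_filters(av, config)

  index <- if (inherits(cohort, "cohort_index")) cohort
           else if (identical(cohort, "rebuild")) build_cohort_index(flt$retained)
           else stop("cohort must be 'rebuild' or a cohort_index")
  pri <- prioritize(flt$retained, index = index, config = config)

  counts <- stage_counts(av, flt$retained, pri$candidates)
  fail_hist <- sort(table(flt$removed$failed_rules), decreasing = TRUE)

  candidates <- pri$candidates
  if (!is.null(evidence)) {
    m <- match(candidates$key, evidence$key)
    cls <- rep(NA_character_, nrow(candidates))
    has <- !is.na(m)
    if (any(has)) cls[has] <- classify_all(evidence[m[has], , drop = FALSE], rules)
    candidates$class <- cls
  }

  coverage <- if (!is.null(profiles)) coverage_summary(profiles) else NULL
  flagged <- if (!is.null(coverage))
    flag_low_coverage(coverage, config$depth_threshold, config$gc_threshold,
                      stat = config$low_coverage_stat) else NULL

  structure(list(stage_counts = counts,
                 candidates = candidates,
                 masked = pri$masked,
                 removed = flt$removed,
                 filter_failures = fail_hist,
                 cohort_size = index$n_patients,
                 coverage = coverage,
                 flagged_regions = flagged,
                 config = unclass(config),
                 seed = seed,
                 versions = list(
                   panelsift = as.character(utils::packageVersion("panelsift")),
                   r = paste(R.version$major, R.version$minor, sep = "."))),
            class = "panel_run_report")
}

#' @export
print.panel_run_report <- function(x, ...) {
  print(x$stage_counts)
  cat("removed by rule(s):\n")
  print(x$filter_failures)
  if (!is.null(x$flagged_regions))
    cat(nrow(x$flagged_regions), "region(s) flagged low-coverage\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `candidates.tsv` (per-patient candidate variants with annotations
#' and, when classified, classes), `masked.tsv` and `removed.tsv` with their
#' reasons, and `report.json` with stage counts, filter-failure histogram,
#' per-gene coverage, flagged regions, configuration echo and versions.
#' Timestamps and hostnames are deliberately absent so identical runs write
#' byte-identical reports.
#'
#' @param report a `panel_run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(report$candidates, "candidates.tsv")
  wr(report$masked, "masked.tsv")
  wr(report$removed, "removed.tsv")
  j <- list(stage_counts = list(per_patient = report$stage_counts$per_patient,
                                means = as.list(report$stage_counts$means)),
            filter_failures = as.list(report$filter_failures),
            cohort_size = report$cohort_size,
            adoc_by_gene = report$coverage$adoc_by_gene,
            overall_adoc = report$coverage$overall_adoc,
            flagged_regions = report$flagged_regions,
            config = report$config,
            seed = report$seed,
            versions = report$versions)
  jsonlite::write_json(j, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
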