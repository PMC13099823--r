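#' Assemble and validate a pipeline configuration
#'
#' A configuration names either a directory of real FAERS-style input
#' (quarter subdirectories plus deleted list and dictionaries, the
#' [write_corpus()] layout) or a synthetic [planted_signal_spec()] — exactly
#' one of the two — together with the target drug, detection thresholds,
#' MGPS prior, BCPNN controls and an optional output directory.
#'
#' @param input_dir Directory of real input tables (or NULL).
#' @param synthetic A [planted_signal_spec()] (or NULL).
#' @param target_drug Target generic name; defaults to the synthetic spec's
#'   drug when a spec is given.
#' @param min_count Minimum target count per evaluated PT.
#' @param n_draws,seed BCPNN Monte-Carlo controls.
#' @param ic_method `"mc"` or `"closed"` information-component computation.
#' @param prior [mgps_prior()] or `"fit"`.
#' @param output_dir Optional directory for exported result tables.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL,
                            target_drug = NULL, min_count = 3,
                            n_draws = 1e5, seed = 20251,
                            ic_method = "mc", prior = mgps_prior(),
                            output_dir = NULL) {
  if (is.null(input_dir) == is.null(synthetic)) {
    stop("provide exactly one of input_dir or synthetic")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "planted_signal_spec")) {
    stop("synthetic must be a planted_signal_spec")
  }
  if (is.null(target_drug)) {
    if (is.null(synthetic)) stop("target_drug is required with real input")
    target_drug <- synthetic$target_drug
  }
  if (min_count <= 0 || n_draws <= 0) stop("thresholds must be positive")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 target_drug = target_drug, min_count = min_count,
                 n_draws = n_draws, seed = seed, ic_method = ic_method,
                 prior = prior, output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `synthetic:`
#' block holds [planted_signal_spec()] arguments (with `associations` and
#' `background_pts` as lists of column vectors).
#'
#' @param file YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    for (f in c("associations", "background_pts")) {
      if (!is.null(s[[f]])) s[[f]] <- as.data.frame(s[[f]], stringsAsFactors = FALSE)
    }
    y$synthetic <- do.call(planted_signal_spec, s)
  }
  if (!is.null(y$prior) && !identical(y$prior, "fit")) {
    y$prior <- do.call(mgps_prior, y$prior)
  }
  do.call(pipeline_config, y)
}

#' Run the full signal-detection pipeline
#'
#' Stages, in order: input acquisition (read or generate), deduplication,
#' deleted-report removal, case assembly, target/background split,
#' contingency tables, four-algorithm signal detection, time-to-onset
#' Weibull analysis, sex/age/report-type subgroup screens, and the
#' descriptive tables. A manifest records the count entering and leaving
#' every stage; identical config and seed give an identical manifest.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return A list of class `pipeline_run`: `manifest` (stage counts),
#'   `cases`, `target`, `background`, `signals`, `tto` (records, exclusions
#'   and `weibull_fit` when at least 10 onsets survive), `subgroups`,
#'   `sex_difference`, `characteristics`, `soc`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$synthetic)) {
    corpus <- generate_corpus(config$synthetic)
    tables <- corpus_tables(corpus)
    deleted <- corpus$deleted
    dict <- dictionary_tables(corpus$dict$pt_to_soc, corpus$dict$drug_synonyms)
  } else {
    inp <- read_corpus_dir(config$input_dir)
    tables <- inp$tables
    deleted <- inp$deleted
    dict <- inp$dict
  }
  cleaned <- clean_faers(tables, deleted, dict)
  cases <- cleaned$cases
  pop <- select_target_population(cases, config$target_drug)
  if (n_reports(pop$target) == 0L) {
    stop("stage target-split failed: no reports with PS drug '",
         config$target_drug, "'")
  }
  tabs <- build_contingency_tables(pop$target, pop$background)
  signals <- detect_signals(tabs, min_count = config$min_count,
                            prior = config$prior, n_draws = config$n_draws,
                            seed = config$seed, ic_method = config$ic_method)
  tto <- compute_tto(pop$target)
  wb <- if (nrow(tto$records) >= 10L &&
              length(unique(tto$records$tto_days)) > 1L) {
    fit_weibull(tto$records)
  } else NULL

  subgroup_specs <- list(c("sex", "F"), c("sex", "M"),
                         c("age_group", "<65"), c("age_group", ">=65"),
                         c("report_type", "serious"),
                         c("report_type", "non-serious"))
  subgroups <- lapply(subgroup_specs, function(s) {
    tryCatch(stratified_signals(pop$target, pop$background, s[1], s[2],
                                min_count = config$min_count),
             warning = function(w) NULL)
  })
  names(subgroups) <- vapply(subgroup_specs, paste, "", collapse = ":")

  sexdiff <- if (any(pop$target$reports$sex == "F") &&
                   any(pop$target$reports$sex == "M")) {
    sex_difference(pop$target)
  } else NULL

  manifest <- list(
    demo_rows_in = cleaned$counts$demo_rows_in,
    duplicates_removed = cleaned$counts$duplicates_removed,
    fda_dt_rejects = cleaned$counts$fda_dt_rejects,
    deleted_removed = cleaned$counts$deleted_removed,
    reports_clean = n_reports(cases),
    n_target = n_reports(pop$target),
    n_background = n_reports(pop$background),
    n_pts_tabulated = nrow(tabs),
    n_pts_evaluated = nrow(signals),
    n_consensus_signals = sum(signals$consensus),
    tto_included = nrow(tto$records),
    tto_excluded = unclass(tto$excluded),
    seed = config$seed
  )

  out <- list(manifest = manifest, cases = cases, target = pop$target,
              background = pop$background, tables = tabs, signals = signals,
              tto = c(tto, list(fit = wb)),
              subgroups = subgroups, sex_difference = sexdiff,
              characteristics = characteristics_table(pop$target),
              soc = soc_distribution(pop$target))
  class(out) <- "pipeline_run"
  if (!is.null(config$output_dir)) export_run(out, config$output_dir)
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_run>\n",
      "  reports after cleaning: ", m$reports_clean,
      " (", m$duplicates_removed, " duplicates, ", m$deleted_removed,
      " deleted removed)\n",
      "  target / background:    ", m$n_target, " / ", m$n_background, "\n",
      "  consensus signals:      ", m$n_consensus_signals, " of ",
      m$n_pts_evaluated, " PTs evaluated\n",
      "  onset records:          ", m$tto_included, "\n", sep = "")
  invisible(x)
}

#' Export the delimited result tables of a pipeline run
#'
#' Writes `signals.tsv`, `characteristics.tsv`, `soc_distribution.tsv`,
#' `tto_records.tsv`, `weibull.tsv` (when fitted), per-stratum subgroup
#' tables, `sex_difference.tsv` and `manifest.yaml` under `dir`.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(run$signals, "signals.tsv")
  wt(run$characteristics, "characteristics.tsv")
  wt(run$soc, "soc_distribution.tsv")
  wt(run$tto$records, "tto_records.tsv")
  if (!is.null(run$tto$fit)) wt(weibull_summary_table(run$tto$fit), "weibull.tsv")
  for (nm in names(run$subgroups)) {
    if (!is.null(run$subgroups[[nm]])) {
      wt(run$subgroups[[nm]], paste0("subgroup_", gsub("[:<>=]", "_", nm), ".tsv"))
    }
  }
  if (!is.null(run$sex_difference)) wt(run$sex_difference, "sex_difference.tsv")
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
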