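#' Deduplicate DEMO rows to one report per case
#'
#' FAERS re-publishes amended reports under the same CASEID across quarters.
#' Following the archive's own deduplication rule, rows are sorted by CASEID,
#' FDA_DT and PRIMARYID; within a CASEID the row with the latest FDA receipt
#' date is retained, and among rows sharing the latest date the one with the
#' largest PRIMARYID.
#'
#' @param demo A DEMO data.frame with (at least) `caseid`, `fda_dt`,
#'   `primaryid` columns.
#' @return A list with components `kept` (one row per CASEID, sorted by
#'   caseid, fda_dt, primaryid), `removed` (the superseded duplicate rows) and
#'   `rejects` (rows whose FDA_DT could not be parsed to a complete date —
#'   quarantined, not silently dropped).
#' @export
deduplicate_reports <- function(demo) {
  required <- c("caseid", "fda_dt", "primaryid")
  missing_cols <- setdiff(required, names(demo))
  if (length(missing_cols)) {
    stop("DEMO lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  fda <- parse_faers_date(demo$fda_dt)
  bad <- fda$status != "complete"
  rejects <- demo[bad, , drop = FALSE]
  demo <- demo[!bad, , drop = FALSE]
  if (nrow(demo) == 0L) {
    return(list(kept = demo, removed = demo, rejects = rejects))
  }
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, fda$date[!bad], pid_num)
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  list(kept = demo[keep, , drop = FALSE],
       removed = demo[!keep, , drop = FALSE],
       rejects = rejects)
}

#' Remove reports whose CASEID is on a deleted-case list
#'
#' Since 2019Q1 every FAERS quarter ships a list of case identifiers whose
#' reports were deleted; surviving analysis sets must drop them after
#' deduplication.
#'
#' @param demo Deduplicated DEMO data.frame.
#' @param deleted_caseids Character vector of CASEIDs (an empty vector is a
#'   no-op).
#' @return A list with `kept`, `removed` data.frames and `n_removed`.
#' @export
remove_deleted_cases <- function(demo, deleted_caseids) {
  deleted_caseids <- trimws(as.character(deleted_caseids))
  deleted_caseids <- deleted_caseids[nzchar(deleted_caseids)]
  hit <- demo$caseid %in% deleted_caseids
  if (all(hit) && nrow(demo) > 0L) {
    warning("deleted-case list removed every report")
  }
  list(kept = demo[!hit, , drop = FALSE],
       removed = demo[hit, , drop = FALSE],
       n_removed = sum(hit))
}

#' Read a deleted-case list (one CASEID per line)
#' @param file Path to a plain-text file.
#' @return Character vector of CASEIDs.
#' @export
read_deleted_list <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[nzchar(x)]
}

#' Assemble dictionary tables for term and drug-name standardization
#'
#' @param pt_to_soc Either a two-column data.frame (`pt`, `soc`) or the path
#'   to a tab-separated file with those columns. One primary SOC per PT.
#' @param drug_synonyms Either a two-column data.frame (`raw`, `generic`) or a
#'   TSV path. Maps verbatim drug-name spellings to standardized generic
#'   names.
#' @return An object of class `dictionary_tables`. Lookups are
#'   case-insensitive after whitespace normalization.
#' @export
dictionary_tables <- function(pt_to_soc, drug_synonyms) {
  read_tsv2 <- function(x, cols) {
    if (is.character(x) && length(x) == 1L) {
      x <- utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character")
    }
    names(x) <- tolower(names(x))
    if (!all(cols %in% names(x))) {
      stop("dictionary table needs columns: ", paste(cols, collapse = ", "))
    }
    x[cols]
  }
  pts <- read_tsv2(pt_to_soc, c("pt", "soc"))
  key <- norm_term(pts$pt)
  if (anyDuplicated(key)) {
    dup <- pts$pt[duplicated(key)][1L]
    stop("PT maps to more than one SOC: ", dup)
  }
  syn <- read_tsv2(drug_synonyms, c("raw", "generic"))
  structure(list(
    pt_soc = stats::setNames(pts$soc, key),
    synonyms = stats::setNames(norm_term(syn$generic), norm_term(syn$raw))
  ), class = "dictionary_tables")
}

# whitespace-normalized, case-folded term key
norm_term <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' @export
print.dictionary_tables <- function(x, ...) {
  cat("<dictionary_tables> ", length(x$pt_soc), " PT->SOC mappings, ",
      length(x$synonyms), " drug synonyms\n", sep = "")
  invisible(x)
}

#' Assemble an analysis-ready case set from cleaned FAERS tables
#'
#' Joins the deduplicated, deletion-filtered DEMO table with DRUG, REAC, OUTC
#' and THER rows to one structured record per surviving report: demographics
#' (age in years with stratum, sex, country, reporter occupation, report
#' year), aggregated outcome codes with a seriousness flag, standardized drug
#' list with role codes, the preferred-term event list with its system organ
#' class, and report-level therapy-start / event dates for onset analysis.
#'
#' @param tables Named list of FAERS data.frames; `DEMO`, `DRUG`, `REAC` are
#'   required, `OUTC` and `THER` optional.
#' @param dict A [dictionary_tables()] object.
#' @return An object of class `faers_cases`: a list of data.frames `reports`
#'   (one row per report), `drugs`, `events`, `outcomes`, plus a `log` of
#'   counts (orphan rows, unmapped names/terms).
#' @details
#' * Ages are converted to years from the `age_cod` unit (decades, months,
#'   weeks, days, hours supported); unknown units become missing.
#' * A report is *serious* iff any outcome code in DE/LT/HO/DS/CA/RI is
#'   present; OT-only or no outcome is non-serious.
#' * Drug names are passed through the synonym table; unmapped names are kept
#'   verbatim (lower-cased) and flagged `mapped = FALSE`.
#' * Repeated identical PTs within one report collapse to a single event.
#' * Therapy start is the earliest complete `start_dt` among THER rows linked
#'   to the report's primary-suspect drug sequence(s); the event date is the
#'   DEMO `event_dt`.
#' * DRUG/REAC/OUTC/THER rows whose PRIMARYID is absent from DEMO are counted
#'   in the log and excluded.
#' @export
assemble_cases <- function(tables, dict) {
  names(tables) <- toupper(names(tables))
  for (t in c("DEMO", "DRUG", "REAC")) {
    if (is.null(tables[[t]])) stop("assemble_cases needs a ", t, " table")
  }
  demo <- tables$DEMO
  ids <- demo$primaryid
  if (anyDuplicated(ids)) stop("DEMO has duplicated PRIMARYIDs; deduplicate first")

  get_col <- function(df, col) if (col %in% names(df)) df[[col]] else rep("", nrow(df))

  fda <- parse_faers_date(get_col(demo, "fda_dt"))
  evt <- parse_faers_date(get_col(demo, "event_dt"))
  age_years <- age_to_years(get_col(demo, "age"), get_col(demo, "age_cod"))
  sex <- toupper(trimws(get_col(demo, "sex")))
  sex[!sex %in% c("F", "M")] <- "unknown"
  occp <- REPORTER_MAP[toupper(trimws(get_col(demo, "occp_cod")))]
  occp[is.na(occp)] <- "unknown"
  country <- trimws(get_col(demo, "occr_country"))
  country[!nzchar(country)] <- "unknown"

  keep_rows <- function(df) {
    if (is.null(df) || nrow(df) == 0L) {
      return(list(df = df[0L, , drop = FALSE], orphans = 0L))
    }
    ok <- df$primaryid %in% ids
    list(df = df[ok, , drop = FALSE], orphans = sum(!ok))
  }
  drug <- keep_rows(tables$DRUG)
  reac <- keep_rows(tables$REAC)
  outc <- keep_rows(tables$OUTC)
  ther <- keep_rows(tables$THER)

  # drug standardization through the synonym table
  raw_names <- norm_term(get_col(drug$df, "drugname"))
  std <- unname(dict$synonyms[raw_names])
  mapped <- !is.na(std)
  std[!mapped] <- raw_names[!mapped]
  drugs <- data.frame(
    primaryid = drug$df$primaryid,
    drug_seq = get_col(drug$df, "drug_seq"),
    name_raw = get_col(drug$df, "drugname"),
    name = std,
    role = toupper(trimws(get_col(drug$df, "role_cod"))),
    mapped = mapped,
    stringsAsFactors = FALSE
  )

  # events: one PT occurrence per report, with primary SOC
  pts_raw <- trimws(get_col(reac$df, "pt"))
  ev <- data.frame(primaryid = reac$df$primaryid, pt = norm_term(pts_raw),
                   stringsAsFactors = FALSE)
  ev <- ev[nzchar(ev$pt), , drop = FALSE]
  ev <- ev[!duplicated(ev[c("primaryid", "pt")]), , drop = FALSE]
  soc <- unname(dict$pt_soc[ev$pt])
  events <- data.frame(primaryid = ev$primaryid, pt = ev$pt,
                       soc = ifelse(is.na(soc), "unmapped", soc),
                       stringsAsFactors = FALSE)

  outcomes <- data.frame(primaryid = character(0), outc_cod = character(0))
  if (!is.null(outc$df) && nrow(outc$df)) {
    oc <- data.frame(primaryid = outc$df$primaryid,
                     outc_cod = toupper(trimws(get_col(outc$df, "outc_cod"))),
                     stringsAsFactors = FALSE)
    oc <- oc[oc$outc_cod %in% OUTCOME_CODES, , drop = FALSE]
    outcomes <- oc[!duplicated(oc), , drop = FALSE]
  }
  serious_ids <- unique(outcomes$primaryid[outcomes$outc_cod %in% SERIOUS_OUTCOMES])

  # therapy start: earliest complete start among PS-drug THER rows
  therapy_start <- rep(as.Date(NA), nrow(demo))
  therapy_status <- rep("missing", nrow(demo))
  names(therapy_start) <- names(therapy_status) <- ids
  if (!is.null(ther$df) && nrow(ther$df)) {
    ps <- drugs[drugs$role == "PS", c("primaryid", "drug_seq")]
    th <- ther$df
    th_seq <- get_col(th, "dsg_drug_seq")
    key_th <- paste(th$primaryid, th_seq)
    key_ps <- paste(ps$primaryid, ps$drug_seq)
    th <- th[key_th %in% key_ps, , drop = FALSE]
    if (nrow(th)) {
      sd <- parse_faers_date(get_col(th, "start_dt"))
      by_id <- split(seq_len(nrow(th)), th$primaryid)
      for (id in names(by_id)) {
        i <- by_id[[id]]
        comp <- i[sd$status[i] == "complete"]
        if (length(comp)) {
          therapy_start[id] <- min(sd$date[comp])
          therapy_status[id] <- "complete"
        } else if (any(sd$status[i] == "incomplete")) {
          therapy_status[id] <- "incomplete"
        }
      }
    }
  }

  reports <- data.frame(
    primaryid = ids,
    caseid = get_col(demo, "caseid"),
    fda_dt = fda$date,
    report_year = as.integer(format(fda$date, "%Y")),
    sex = sex,
    age_years = age_years,
    age_group = age_group(age_years),
    country = country,
    reporter = unname(occp),
    serious = ids %in% serious_ids,
    event_date = evt$date,
    event_date_status = evt$status,
    therapy_start = unname(therapy_start),
    therapy_start_status = unname(therapy_status),
    stringsAsFactors = FALSE
  )

  structure(list(
    reports = reports,
    drugs = drugs,
    events = events,
    outcomes = outcomes,
    log = list(orphan_drug = drug$orphans, orphan_reac = reac$orphans,
               orphan_outc = outc$orphans, orphan_ther = ther$orphans,
               unmapped_drug_names = sum(!mapped),
               unmapped_pts = sum(events$soc == "unmapped"))
  ), class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$reports), " reports, ",
      nrow(x$events), " report-PT events, ",
      nrow(x$drugs), " drug rows\n", sep = "")
  invisible(x)
}

#' Number of reports in a case set
#' @param cases A `faers_cases` object.
#' @return Integer report count.
#' @export
n_reports <- function(cases) nrow(cases$reports)

# restrict a faers_cases object to a set of primaryids
subset_cases <- function(cases, ids) {
  out <- cases
  out$reports <- cases$reports[cases$reports$primaryid %in% ids, , drop = FALSE]
  for (nm in c("drugs", "events", "outcomes")) {
    out[[nm]] <- cases[[nm]][cases[[nm]]$primaryid %in% ids, , drop = FALSE]
  }
  out
}

#' Split a case set into target-drug and background populations
#'
#' A report belongs to the target population iff its primary-suspect (PS)
#' drug equals the target generic name (case-insensitive, after
#' standardization). Reports without a PS-role drug, or with a different PS
#' drug — including ones that carry the target only as secondary suspect or
#' concomitant — form the background. The partition is exhaustive and
#' disjoint.
#'
#' @param cases A `faers_cases` object.
#' @param target_drug Standardized generic name.
#' @return A list with `target` and `background` (`faers_cases`), plus
#'   `n_no_ps`, the number of reports lacking any PS-role drug.
#' @export
select_target_population <- function(cases, target_drug) {
  key <- norm_term(target_drug)
  ps <- cases$drugs[cases$drugs$role == "PS", , drop = FALSE]
  target_ids <- unique(ps$primaryid[ps$name == key])
  all_ids <- cases$reports$primaryid
  list(target = subset_cases(cases, target_ids),
       background = subset_cases(cases, setdiff(all_ids, target_ids)),
       n_no_ps = sum(!all_ids %in% unique(ps$primaryid)))
}

#' Run the full cleaning chain on raw quarterly tables
#'
#' Convenience wrapper: deduplicate DEMO, drop deleted cases, restrict the
#' satellite tables to surviving reports, and assemble the case set.
#'
#' @param tables Named list of raw FAERS data.frames (quarters already
#'   concatenated per table).
#' @param deleted_caseids Character vector of deleted CASEIDs.
#' @param dict A [dictionary_tables()] object.
#' @return A list: `cases` (`faers_cases`), and `counts` with per-stage
#'   bookkeeping (rows in, duplicates removed, rejects, deleted removed).
#' @export
clean_faers <- function(tables, deleted_caseids, dict) {
  names(tables) <- toupper(names(tables))
  dd <- deduplicate_reports(tables$DEMO)
  rm <- remove_deleted_cases(dd$kept, deleted_caseids)
  tables$DEMO <- rm$kept
  cases <- assemble_cases(tables, dict)
  list(cases = cases,
       counts = list(demo_rows_in = nrow(dd$kept) + nrow(dd$removed) + nrow(dd$rejects),
                     duplicates_removed = nrow(dd$removed),
                     fda_dt_rejects = nrow(dd$rejects),
                     deleted_removed = rm$n_removed,
                     reports_out = nrow(rm$kept)))
}

#' Write a case set to delimited tables
#'
#' Exports the four component tables (`reports`, `drugs`, `events`,
#' `outcomes`) as tab-separated files with dates in ISO format; the column
#' contract is exactly what [assemble_cases()] produces, so
#' [read_cases()] on the written directory round-trips the case set.
#'
#' @param cases A `faers_cases` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cases <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("reports", "drugs", "events", "outcomes")) {
    df <- cases[[nm]]
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(dir)
}

#' Read a case set written by [write_cases()]
#'
#' @param dir Directory holding `reports.tsv`, `drugs.tsv`, `events.tsv`,
#'   `outcomes.tsv`.
#' @return A `faers_cases` object (with an empty ingestion log).
#' @export
read_cases <- function(dir) {
  rd <- function(nm) utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                                       stringsAsFactors = FALSE,
                                       colClasses = "character", na.strings = NULL)
  reports <- rd("reports")
  reports$fda_dt <- as.Date(reports$fda_dt)
  reports$event_date <- as.Date(ifelse(nzchar(reports$event_date),
                                       reports$event_date, NA))
  reports$therapy_start <- as.Date(ifelse(nzchar(reports$therapy_start),
                                          reports$therapy_start, NA))
  reports$report_year <- as.integer(reports$report_year)
  reports$age_years <- suppressWarnings(as.numeric(reports$age_years))
  reports$serious <- reports$serious == "TRUE"
  drugs <- rd("drugs")
  drugs$mapped <- drugs$mapped == "TRUE"
  structure(list(reports = reports, drugs = drugs, events = rd("events"),
                 outcomes = rd("outcomes"), log = list()),
            class = "faers_cases")
}
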