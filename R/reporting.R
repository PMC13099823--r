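#' Round half up to a fixed number of decimals
#'
#' Commercial rounding (0.005 -> 0.01), as printed frequency tables
#' conventionally use; `base::round` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

freq_rows <- function(section, labels, counts, denom) {
  data.frame(section = section, label = labels, count = as.integer(counts),
             pct = round_half_up(100 * counts / denom, 2),
             stringsAsFactors = FALSE)
}

#' Descriptive characteristics table of a report population
#'
#' Sectioned frequency table over the cleaned target population: sex, age
#' group, report year, reporter occupation, top-5 reporting countries,
#' outcome codes, and the onset-time buckets (with a missing/negative row).
#' Percentages use the report count as denominator and are rounded half-up
#' to two decimals. The outcome section counts reports once per outcome code,
#' so a report with several outcomes appears in several rows and the section
#' may exceed 100%.
#'
#' @param cases A `faers_cases` object.
#' @param top_countries How many countries to list (default 5).
#' @return data.frame with columns `section`, `label`, `count`, `pct`.
#' @export
characteristics_table <- function(cases, top_countries = 5) {
  r <- cases$reports
  denom <- nrow(r)
  if (denom == 0L) stop("empty case set")
  out <- list()

  sex_lab <- c(F = "Female", M = "Male", unknown = "Not specified")
  sx <- table(factor(r$sex, levels = names(sex_lab)))
  out$sex <- freq_rows("sex", unname(sex_lab), as.integer(sx), denom)

  ag <- table(factor(r$age_group, levels = AGE_GROUP_LEVELS))
  ag_lab <- c("<18", "18-44", "45-64", ">=65", "Not specified")
  out$age <- freq_rows("age_group", ag_lab, as.integer(ag), denom)

  yrs <- sort(unique(r$report_year[!is.na(r$report_year)]))
  if (length(yrs)) {
    yt <- table(factor(r$report_year, levels = yrs))
    out$year <- freq_rows("report_year", as.character(yrs), as.integer(yt), denom)
  }

  rep_lab <- c(consumer = "Consumer", unknown = "Not specified",
               `other-health-professional` = "Other health-professional",
               pharmacist = "Pharmacist", physician = "Physician")
  rt <- table(factor(r$reporter, levels = names(rep_lab)))
  out$reporter <- freq_rows("reporter", unname(rep_lab), as.integer(rt), denom)

  ct <- sort(table(r$country[r$country != "unknown"]), decreasing = TRUE)
  ct <- utils::head(ct, top_countries)
  if (length(ct)) {
    out$country <- freq_rows("country", names(ct), as.integer(ct), denom)
  }

  oc_lab <- c(LT = "Life-threatening", HO = "Hospitalization - initial or prolonged",
              DS = "Disability", DE = "Death", CA = "Congenital anomaly",
              RI = "Required intervention to prevent permanent impairment/Damage",
              OT = "Other")
  ot <- table(factor(cases$outcomes$outc_cod, levels = names(oc_lab)))
  out$outcomes <- freq_rows("outcomes", unname(oc_lab), as.integer(ot), denom)

  tto <- compute_tto(cases)
  bd <- bucket_distribution(tto$records)
  out$tto <- rbind(
    freq_rows("tto_bucket", paste0(names(bd), " d"), as.integer(bd), denom),
    freq_rows("tto_bucket", "Missing or outlier (<0)", sum(tto$excluded), denom)
  )
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' System-organ-class distribution of adverse-event instances, with tiers
#'
#' Aggregates report-PT pairs (AE instances) by their primary SOC; the
#' denominator is the total instance count. Tier labels follow the usual
#' frequency bands: *primary* above 5%, *secondary* between 1% and 5%
#' (inclusive), *rare* below 1%. SOCs with zero events are omitted; PTs
#' without a dictionary mapping aggregate into an explicit `unmapped` row.
#'
#' @param cases A `faers_cases` object.
#' @return data.frame `soc`, `count`, `pct`, `tier`, sorted by descending
#'   count.
#' @export
soc_distribution <- function(cases) {
  ev <- cases$events
  if (nrow(ev) == 0L) stop("no events")
  tab <- sort(table(ev$soc), decreasing = TRUE)
  pct <- round_half_up(100 * as.integer(tab) / nrow(ev), 2)
  tier <- ifelse(pct > 5, "primary", ifelse(pct >= 1, "secondary", "rare"))
  data.frame(soc = names(tab), count = as.integer(tab), pct = pct,
             tier = tier, stringsAsFactors = FALSE, row.names = NULL)
}

#' Outcome distribution across selected preferred terms
#'
#' For each PT, counts reports that carry the PT per outcome code; a report
#' with several outcome codes contributes once to each of its codes.
#'
#' @param cases A `faers_cases` object.
#' @param top_pts Character vector of PTs (e.g. the top consensus signals).
#' @return Integer matrix, PTs in rows, the seven outcome codes in columns.
#' @export
outcome_by_pt <- function(cases, top_pts) {
  ev <- cases$events[cases$events$pt %in% top_pts, , drop = FALSE]
  oc <- cases$outcomes
  m <- matrix(0L, length(top_pts), length(OUTCOME_CODES),
              dimnames = list(top_pts, OUTCOME_CODES))
  if (nrow(ev) && nrow(oc)) {
    j <- merge(ev[c("primaryid", "pt")], oc, by = "primaryid")
    if (nrow(j)) {
      t2 <- table(factor(j$pt, levels = top_pts),
                  factor(j$outc_cod, levels = OUTCOME_CODES))
      m <- matrix(as.integer(t2), nrow(t2), ncol(t2),
                  dimnames = list(top_pts, OUTCOME_CODES))
    }
  }
  m
}

#' Top-k listing of signal results
#'
#' @param signals A [detect_signals()] result.
#' @param k Number of rows (default 50).
#' @param by `"ror"` (descending ROR, the signal-strength convention) or
#'   `"frequency"` (descending `a`, the subgroup convention); ties by larger
#'   `a`, then PT.
#' @param consensus_only Keep only all-four consensus signals (default TRUE
#'   when the column is present).
#' @return The top-k rows of `signals`.
#' @export
top_signals <- function(signals, k = 50, by = c("ror", "frequency"),
                        consensus_only = "consensus" %in% names(signals)) {
  by <- match.arg(by)
  x <- signals
  if (isTRUE(consensus_only) && "consensus" %in% names(x)) {
    x <- x[x$consensus, , drop = FALSE]
  }
  ord <- if (by == "ror") order(-x$ror, -x$a, x$pt) else order(-x$a, x$pt)
  utils::head(x[ord, , drop = FALSE], k)
}
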