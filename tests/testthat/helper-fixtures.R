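# Programmatic fixtures shared across the suite.

# Build a faers_cases object directly from its component tables, filling the
# column contract with sensible defaults so tests only state what they vary.
make_cases <- function(n,
                       sex = rep("F", n),
                       age_years = rep(50, n),
                       country = rep("US", n),
                       reporter = rep("physician", n),
                       report_year = rep(2021L, n),
                       event_date = rep(as.Date("2021-06-01"), n),
                       therapy_start = rep(as.Date("2021-05-01"), n),
                       events = NULL,
                       outcomes = NULL,
                       drugs = NULL) {
  ids <- sprintf("p%04d", seq_len(n))
  ev_status <- ifelse(is.na(event_date), "missing", "complete")
  th_status <- ifelse(is.na(therapy_start), "missing", "complete")
  if (is.null(events)) {
    events <- data.frame(primaryid = character(0), pt = character(0),
                         soc = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(outcomes)) {
    outcomes <- data.frame(primaryid = character(0), outc_cod = character(0),
                           stringsAsFactors = FALSE)
  }
  if (is.null(drugs)) {
    drugs <- data.frame(primaryid = ids, drug_seq = rep("1", n),
                        name_raw = rep("drug", n), name = rep("drug", n),
                        role = rep("PS", n), mapped = rep(TRUE, n),
                        stringsAsFactors = FALSE)
  }
  serious_ids <- unique(outcomes$primaryid[outcomes$outc_cod %in%
                                             c("DE", "LT", "HO", "DS", "CA", "RI")])
  reports <- data.frame(
    primaryid = ids, caseid = ids,
    fda_dt = as.Date(sprintf("%d-03-15", as.integer(report_year))),
    report_year = as.integer(report_year),
    sex = sex, age_years = age_years, age_group = faersignal::age_group(age_years),
    country = country, reporter = reporter,
    serious = ids %in% serious_ids,
    event_date = event_date, event_date_status = ev_status,
    therapy_start = therapy_start, therapy_start_status = th_status,
    stringsAsFactors = FALSE
  )
  structure(list(reports = reports, drugs = drugs, events = events,
                 outcomes = outcomes, log = list()),
            class = "faers_cases")
}

# events table helper: pt_by_report is a named list primaryid index -> PTs
make_events <- function(ids, pt_list, soc = "soc1") {
  do.call(rbind, lapply(seq_along(pt_list), function(i) {
    pts <- pt_list[[i]]
    if (length(pts) == 0) return(NULL)
    data.frame(primaryid = ids[i], pt = pts, soc = soc, stringsAsFactors = FALSE)
  }))
}

# random small 2x2 tables for oracle-equivalence properties
random_tables <- function(n, seed, max_cell = 200) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE) + 20L,
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell * 10, n, replace = TRUE) + 50L)
}

# tiny dictionary used by ingestion tests
tiny_dict <- function() {
  dictionary_tables(
    data.frame(pt = c("stomatitis", "nausea", "rash"),
               soc = c("gastrointestinal disorders", "gastrointestinal disorders",
                       "skin and subcutaneous tissue disorders"),
               stringsAsFactors = FALSE),
    data.frame(raw = c("FOLOTYN", "MTX"),
               generic = c("pralatrexate", "methotrexate"),
               stringsAsFactors = FALSE)
  )
}

# raw quarterly-style tables for a handful of reports
tiny_raw_tables <- function() {
  demo <- data.frame(
    primaryid = c("11", "21", "31", "41"),
    caseid = c("1", "2", "3", "4"),
    fda_dt = c("20210110", "20210215", "20210320", "20210401"),
    event_dt = c("20210105", "202102", "", "20210330"),
    age = c("72", "6", "730", ""),
    age_cod = c("YR", "DEC", "DY", ""),
    sex = c("F", "M", "", "F"),
    occp_cod = c("MD", "CN", "PH", ""),
    occr_country = c("US", "JP", "", "GB"),
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    primaryid = c("11", "11", "21", "31", "41", "99"),
    caseid = c("1", "1", "2", "3", "4", "9"),
    drug_seq = c("1", "2", "1", "1", "1", "1"),
    role_cod = c("PS", "C", "PS", "C", "PS", "PS"),
    drugname = c("FOLOTYN", "folic acid", "MTX", "FOLOTYN", "unknowndrug", "MTX"),
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    primaryid = c("11", "11", "11", "21", "31", "41", "99"),
    caseid = c("1", "1", "1", "2", "3", "4", "9"),
    pt = c("Stomatitis", "stomatitis", "nausea", "rash", "nausea", "mystery pt", "rash"),
    stringsAsFactors = FALSE
  )
  outc <- data.frame(
    primaryid = c("11", "11", "21", "41"),
    caseid = c("1", "1", "2", "4"),
    outc_cod = c("HO", "OT", "OT", "DE"),
    stringsAsFactors = FALSE
  )
  ther <- data.frame(
    primaryid = c("11", "11", "21", "41"),
    caseid = c("1", "1", "2", "4"),
    dsg_drug_seq = c("1", "1", "1", "1"),
    start_dt = c("20210102", "20201230", "202101", "20210325"),
    end_dt = c("", "", "", ""),
    stringsAsFactors = FALSE
  )
  list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc, THER = ther)
}
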