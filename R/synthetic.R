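# default background PT pool: common oncology-cohort reactions with
# plausible spontaneous-report baselines
default_background_pts <- function() {
  data.frame(
    pt = c("nausea", "fatigue", "vomiting", "diarrhoea", "pyrexia",
           "headache", "rash", "dyspnoea", "constipation", "oedema peripheral",
           "cough", "dizziness", "pruritus", "abdominal pain", "asthenia",
           "insomnia", "arthralgia", "back pain", "hypertension", "pneumonia",
           "urinary tract infection", "epistaxis", "alopecia", "mucosal dryness",
           "weight decreased", "chills", "malaise", "night sweats",
           "hypokalaemia", "tachycardia"),
    baseline = rep(c(0.06, 0.05, 0.04, 0.03, 0.02, 0.015), each = 5),
    stringsAsFactors = FALSE
  )
}

# planted target-drug associations: antifolate-class toxicities with a
# strong relative reporting rate against a 1% baseline
default_associations <- function() {
  data.frame(
    pt = c("stomatitis", "mucosal inflammation", "thrombocytopenia",
           "neutrophil count decreased", "anaemia", "toxic epidermal necrolysis"),
    rr = c(20, 15, 12, 10, 8, 6),
    baseline = rep(0.01, 6),
    stringsAsFactors = FALSE
  )
}

default_demographic_mix <- function() {
  # category counts of the 563-report study population, as exact fractions
  list(
    sex = c(F = 200, M = 329, unknown = 34) / 563,
    age_group = c("<18" = 0, "18-44" = 52, "45-64" = 149,
                  ">=65" = 257, unknown = 105) / 563,
    country = c(US = 234, JP = 181, GB = 54, CO = 37, BG = 19, FR = 38) / 563,
    reporter = c(physician = 252, `other-health-professional` = 138,
                 pharmacist = 77, consumer = 75, unknown = 21) / 563,
    # per-code report probabilities; outcomes are multi-valued so these do
    # not form a simplex
    outcomes = c(DE = 0.2575, LT = 0.1030, HO = 0.4316, DS = 0.0178,
                 CA = 0, RI = 0.0018, OT = 0.5755)
  )
}

#' Specification of a synthetic spontaneous-report corpus
#'
#' Defines the ground-truth structure a [generate_corpus()] run embeds:
#' planted drug-event relative reporting rates, population sizes, duplicate
#' and deleted-case contamination, Weibull onset-time parameters,
#' missing-date contamination, and the demographic mix. Defaults mirror the
#' pralatrexate study population this package was validated against: 563
#' target reports; onset times Weibull with scale 45.74 days and shape 0.63;
#' 44% of reports with unusable onset dates; sex/age/country/reporter and
#' outcome frequencies as in its characteristics table. The background
#' population defaults to 20,000 reports — a desk-scale stand-in for a full
#' FAERS background.
#'
#' @param target_drug Generic name of the target drug.
#' @param associations data.frame `pt`, `rr`, `baseline`: target reports
#'   carry the PT with probability `min(1, rr * baseline)`, background
#'   reports with `baseline`.
#' @param background_pts data.frame `pt`, `baseline`: null PTs carried by
#'   target and background reports alike.
#' @param n_target,n_background Report counts for the two populations.
#' @param duplicate_fraction Fraction of cases additionally emitted as a
#'   superseded earlier report version (distinct PRIMARYID, earlier FDA_DT).
#' @param deleted_fraction Extra cases, as a fraction of
#'   `n_target + n_background`, that are emitted and placed on the
#'   deleted-case list.
#' @param tto_scale,tto_shape Weibull scale (days) and shape of the onset
#'   interval `event date - therapy start`, rounded to whole days.
#' @param missing_date_fraction Fraction of reports stripped of one of the
#'   two onset-defining dates.
#' @param demographic_mix Named list of probability maps for `sex`,
#'   `age_group`, `country`, `reporter` (each a simplex) and `outcomes`
#'   (per-code probabilities, multi-valued).
#' @param quarters Quarter labels the corpus is split across.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   spec.
#' @return A validated object of class `planted_signal_spec`.
#' @export
planted_signal_spec <- function(target_drug = "pralatrexate",
                                associations = default_associations(),
                                background_pts = default_background_pts(),
                                n_target = 563,
                                n_background = 20000,
                                duplicate_fraction = 0.05,
                                deleted_fraction = 0.01,
                                tto_scale = 45.74,
                                tto_shape = 0.63,
                                missing_date_fraction = 0.44,
                                demographic_mix = default_demographic_mix(),
                                quarters = c("2024Q2", "2024Q3", "2024Q4", "2025Q1"),
                                seed = 1L) {
  stopifnot(is.character(target_drug), length(target_drug) == 1L)
  if (!all(c("pt", "rr", "baseline") %in% names(associations))) {
    stop("associations needs columns pt, rr, baseline")
  }
  if (any(associations$rr < 0)) stop("relative rates must be >= 0")
  probs <- c(associations$baseline, background_pts$baseline,
             duplicate_fraction, deleted_fraction, missing_date_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (tto_scale <= 0 || tto_shape <= 0) stop("Weibull parameters must be positive")
  if (n_target < 1 || n_background < 1) stop("population sizes must be positive")
  for (ax in c("sex", "age_group", "country", "reporter")) {
    p <- demographic_mix[[ax]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("demographic_mix$", ax, " must be a probability map summing to 1")
    }
  }
  oc <- demographic_mix$outcomes
  if (is.null(oc) || any(oc < 0 | oc > 1)) {
    stop("demographic_mix$outcomes must be per-code probabilities in [0, 1]")
  }
  if (any(duplicated(c(associations$pt, background_pts$pt)))) {
    stop("planted and background PT lists must be disjoint and unique")
  }
  structure(list(
    target_drug = target_drug, associations = associations,
    background_pts = background_pts, n_target = as.integer(n_target),
    n_background = as.integer(n_background),
    duplicate_fraction = duplicate_fraction, deleted_fraction = deleted_fraction,
    tto_scale = tto_scale, tto_shape = tto_shape,
    missing_date_fraction = missing_date_fraction,
    demographic_mix = demographic_mix, quarters = quarters,
    seed = as.integer(seed)
  ), class = "planted_signal_spec")
}

#' @export
print.planted_signal_spec <- function(x, ...) {
  cat("<planted_signal_spec> ", x$n_target, " target + ", x$n_background,
      " background reports, ", nrow(x$associations), " planted PTs, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

quarter_bounds <- function(q) {
  yr <- as.integer(substr(q, 1, 4))
  qn <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", yr, (qn - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))

#' Generate a FAERS-shaped synthetic corpus with planted signals
#'
#' Emits the seven quarterly report tables in the dollar-delimited dialect
#' the ingest functions read, a deleted-case list, a mock PT-to-SOC
#' dictionary plus drug-synonym table covering every emitted term, and a
#' ground-truth record of everything planted. The corpus is a deterministic
#' function of the spec (same spec, same bytes).
#'
#' Structure: each report carries a primary-suspect drug (the target drug for
#' target reports — sometimes under a brand-name spelling the synonym table
#' resolves — a background drug otherwise), per-PT independent Bernoulli
#' events (reports with no sampled event receive one background-pool draw, so
#' no report is reaction-free), demographics from the configured mix,
#' outcome codes as independent per-code draws, and a therapy-start /
#' event-date pair whose difference is Weibull-distributed and rounded to
#' whole days. A `duplicate_fraction` of cases is additionally emitted as a
#' superseded earlier version (same CASEID, smaller PRIMARYID, earlier
#' FDA_DT); a `deleted_fraction` of extra cases is emitted and listed in the
#' deleted file; a `missing_date_fraction` of reports loses one onset date.
#'
#' @param spec A [planted_signal_spec()].
#' @param dir Optional directory; when given, one subdirectory per quarter
#'   with `DEMO.txt` ... `RPSR.txt`, plus `deleted.txt`, `pt_soc.tsv`,
#'   `drug_synonyms.tsv` and `ground_truth.yaml` are written.
#' @return Invisibly (visibly when `dir` is NULL) a list: `quarters` (named
#'   list of per-quarter table lists), `deleted` (CASEIDs), `dict`
#'   (`pt_to_soc`, `drug_synonyms` data.frames), `truth` (planted ground
#'   truth: per-PT probabilities, duplicate/deleted CASEIDs, onset
#'   parameters, per-report population labels).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "planted_signal_spec"))
  set.seed(spec$seed)
  mix <- spec$demographic_mix

  n_main <- spec$n_target + spec$n_background
  n_del <- round(spec$deleted_fraction * n_main)
  n_all <- n_main + n_del
  caseid <- as.character(seq(10000001L, length.out = n_all))
  is_target <- c(rep(TRUE, spec$n_target), rep(FALSE, spec$n_background),
                 rep(stats::runif(max(n_del, 1L)) < spec$n_target / n_main,
                     length.out = n_del))
  deleted <- caseid[seq_len(n_del) + n_main]

  # demographics
  sex <- sample_cat(n_all, mix$sex)
  agegrp <- sample_cat(n_all, mix$age_group)
  age <- round(stats::runif(n_all,
                            c("<18" = 2, "18-44" = 18, "45-64" = 45,
                              ">=65" = 65, unknown = 0)[agegrp],
                            c("<18" = 17, "18-44" = 44, "45-64" = 64,
                              ">=65" = 92, unknown = 0)[agegrp]))
  age_chr <- ifelse(agegrp == "unknown", "", as.character(age))
  age_cod <- ifelse(agegrp == "unknown", "", "YR")
  country <- sample_cat(n_all, mix$country)
  occp <- c(physician = "MD", `other-health-professional` = "HP",
            pharmacist = "PH", consumer = "CN", unknown = "")[
              sample_cat(n_all, mix$reporter)]

  # receipt dates within the configured quarters
  qb <- lapply(spec$quarters, quarter_bounds)
  qi <- sample.int(length(spec$quarters), n_all, replace = TRUE)
  fda_dt <- as.Date(vapply(seq_len(n_all), function(i) {
    b <- qb[[qi[i]]]
    as.numeric(b[1] + sample.int(as.integer(b[2] - b[1]) + 1L, 1L) - 1L)
  }, numeric(1L)), origin = "1970-01-01")

  # onset dates: therapy start before receipt, event = start + Weibull days
  onset <- round(stats::rweibull(n_all, shape = spec$tto_shape,
                                 scale = spec$tto_scale))
  ther_start <- fda_dt - sample.int(90L, n_all, replace = TRUE) - onset
  event_dt <- ther_start + onset
  strip <- stats::runif(n_all) < spec$missing_date_fraction
  strip_which <- ifelse(stats::runif(n_all) < 0.5, "start", "event")
  start_out <- fmt_date(ther_start)
  event_out <- fmt_date(event_dt)
  start_out[strip & strip_which == "start"] <- ""
  event_out[strip & strip_which == "event"] <- ""

  # events: per-(report, PT) independent Bernoulli
  all_pts <- rbind(spec$associations[c("pt", "baseline")], spec$background_pts)
  p_target <- c(pmin(1, spec$associations$rr * spec$associations$baseline),
                spec$background_pts$baseline)
  p_backgr <- all_pts$baseline
  n_pt <- nrow(all_pts)
  pmat <- matrix(rep(p_backgr, each = n_all), n_all, n_pt)
  pmat[is_target, ] <- matrix(rep(p_target, each = sum(is_target)),
                              sum(is_target), n_pt)
  hit <- matrix(stats::runif(n_all * n_pt), n_all, n_pt) < pmat
  none <- rowSums(hit) == 0L
  if (any(none)) {
    extra <- sample.int(n_pt, sum(none), replace = TRUE,
                        prob = all_pts$baseline)
    hit[cbind(which(none), extra)] <- TRUE
  }

  # drugs: PS row (target drug under a raw spelling, or a background drug),
  # plus 0-2 concomitants
  target_raw <- c("FOLOTYN", "PRALATREXATE", "Folotyn  (pralatrexate)")
  backgr_drugs <- c("methotrexate", "romidepsin", "belinostat", "bendamustine",
                    "gemcitabine", "cyclophosphamide", "vincristine")
  ps_raw <- ifelse(is_target,
                   target_raw[sample.int(3L, n_all, replace = TRUE)],
                   toupper(backgr_drugs[sample.int(length(backgr_drugs), n_all,
                                                   replace = TRUE)]))
  n_con <- sample.int(3L, n_all, replace = TRUE) - 1L
  con_pool <- c("folic acid", "vitamin b12", "allopurinol", "ondansetron",
                "dexamethasone")

  # outcome codes: independent per-code draws
  oc_names <- names(mix$outcomes)
  oc_hit <- matrix(stats::runif(n_all * length(oc_names)), n_all) <
    matrix(rep(mix$outcomes, each = n_all), n_all)

  primaryid <- paste0(caseid, "2")
  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = "2",
    fda_dt = fmt_date(fda_dt), event_dt = event_out,
    age = age_chr, age_cod = age_cod,
    sex = ifelse(sex == "unknown", "", sex),
    occp_cod = occp, occr_country = country,
    stringsAsFactors = FALSE
  )

  # superseded earlier versions of a fraction of cases
  n_dup <- round(spec$duplicate_fraction * n_main)
  dup_idx <- if (n_dup > 0) sample.int(n_main, n_dup) else integer(0)
  if (length(dup_idx)) {
    dup <- demo[dup_idx, , drop = FALSE]
    dup$primaryid <- paste0(dup$caseid, "1")
    dup$caseversion <- "1"
    dup$fda_dt <- fmt_date(fda_dt[dup_idx] - sample.int(120L, n_dup, replace = TRUE))
    demo <- rbind(demo, dup)
  }

  idx_ev <- which(hit, arr.ind = TRUE)
  reac <- data.frame(primaryid = primaryid[idx_ev[, 1]],
                     caseid = caseid[idx_ev[, 1]],
                     pt = all_pts$pt[idx_ev[, 2]],
                     stringsAsFactors = FALSE)

  con_rows <- rep(seq_len(n_all), n_con)
  drug <- rbind(
    data.frame(primaryid = primaryid, caseid = caseid, drug_seq = "1",
               role_cod = "PS", drugname = ps_raw, stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[con_rows], caseid = caseid[con_rows],
               drug_seq = as.character(unlist(lapply(n_con[n_con > 0], seq_len)) + 1L),
               role_cod = "C",
               drugname = con_pool[sample.int(length(con_pool), length(con_rows),
                                              replace = TRUE)],
               stringsAsFactors = FALSE)
  )

  ther <- data.frame(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = "1", start_dt = start_out, end_dt = "",
                     stringsAsFactors = FALSE)
  ther <- ther[nzchar(ther$start_dt), , drop = FALSE]

  idx_oc <- which(oc_hit, arr.ind = TRUE)
  outc <- data.frame(primaryid = primaryid[idx_oc[, 1]],
                     caseid = caseid[idx_oc[, 1]],
                     outc_cod = oc_names[idx_oc[, 2]],
                     stringsAsFactors = FALSE)

  indi <- data.frame(primaryid = primaryid, caseid = caseid,
                     indi_drug_seq = "1",
                     indi_pt = ifelse(is_target,
                                      "peripheral T-cell lymphoma unspecified",
                                      "neoplasm malignant"),
                     stringsAsFactors = FALSE)
  rpsr <- data.frame(primaryid = primaryid, caseid = caseid,
                     rpsr_cod = "FGN", stringsAsFactors = FALSE)

  # split every table by the quarter of its report's receipt date
  demo_fda <- parse_faers_date(demo$fda_dt)$date
  q_of <- function(d) {
    i <- vapply(as.numeric(d), function(x) {
      hits <- which(vapply(qb, function(b) x >= as.numeric(b[1]) &
                             x <= as.numeric(b[2]), logical(1L)))
      if (length(hits)) hits[1L] else 1L
    }, numeric(1L))
    spec$quarters[i]
  }
  demo_q <- q_of(demo_fda)
  quarters_out <- lapply(spec$quarters, function(q) {
    pid_q <- demo$primaryid[demo_q == q]
    list(DEMO = demo[demo_q == q, , drop = FALSE],
         DRUG = drug[drug$primaryid %in% pid_q, , drop = FALSE],
         REAC = reac[reac$primaryid %in% pid_q, , drop = FALSE],
         OUTC = outc[outc$primaryid %in% pid_q, , drop = FALSE],
         THER = ther[ther$primaryid %in% pid_q, , drop = FALSE],
         INDI = indi[indi$primaryid %in% pid_q, , drop = FALSE],
         RPSR = rpsr[rpsr$primaryid %in% pid_q, , drop = FALSE])
  })
  names(quarters_out) <- spec$quarters

  dict <- synthetic_dictionary(spec)

  truth <- list(
    target_drug = spec$target_drug,
    seed = spec$seed,
    n_target = spec$n_target, n_background = spec$n_background,
    planted = spec$associations,
    tto_scale = spec$tto_scale, tto_shape = spec$tto_shape,
    duplicate_caseids = caseid[dup_idx],
    deleted_caseids = deleted,
    target_caseids = caseid[is_target & !caseid %in% deleted]
  )

  out <- list(quarters = quarters_out, deleted = deleted, dict = dict,
              truth = truth)
  if (!is.null(dir)) {
    write_corpus(out, dir)
    return(invisible(out))
  }
  out
}

# mock dictionary covering every PT and drug spelling the generator emits
synthetic_dictionary <- function(spec) {
  socs <- c("gastrointestinal disorders",
            "general disorders and administration site conditions",
            "blood and lymphatic system disorders",
            "skin and subcutaneous tissue disorders",
            "investigations", "infections and infestations",
            "nervous system disorders", "respiratory, thoracic and mediastinal disorders",
            "metabolism and nutrition disorders",
            "musculoskeletal and connective tissue disorders",
            "vascular disorders", "cardiac disorders", "psychiatric disorders",
            "renal and urinary disorders")
  pts <- c(spec$associations$pt, spec$background_pts$pt)
  pt_to_soc <- data.frame(pt = pts,
                          soc = socs[(seq_along(pts) - 1L) %% length(socs) + 1L],
                          stringsAsFactors = FALSE)
  syn <- data.frame(
    raw = c("FOLOTYN", "PRALATREXATE", "Folotyn  (pralatrexate)",
            "METHOTREXATE", "ROMIDEPSIN", "BELINOSTAT", "BENDAMUSTINE",
            "GEMCITABINE", "CYCLOPHOSPHAMIDE", "VINCRISTINE"),
    generic = c(rep(spec$target_drug, 3), "methotrexate", "romidepsin",
                "belinostat", "bendamustine", "gemcitabine",
                "cyclophosphamide", "vincristine"),
    stringsAsFactors = FALSE
  )
  list(pt_to_soc = pt_to_soc, drug_synonyms = syn)
}

#' Write a generated corpus to disk in the FAERS ASCII layout
#'
#' One subdirectory per quarter holding `DEMO.txt` ... `RPSR.txt`, plus
#' `deleted.txt` (one CASEID per line), `pt_soc.tsv`, `drug_synonyms.tsv`
#' and `ground_truth.yaml` at the top level. The ground-truth sidecar is for
#' validation only and is never read by the analysis path.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (q in names(corpus$quarters)) {
    qd <- file.path(dir, q)
    dir.create(qd, showWarnings = FALSE)
    for (t in names(corpus$quarters[[q]])) {
      write_faers_table(corpus$quarters[[q]][[t]], file.path(qd, paste0(t, ".txt")))
    }
  }
  writeLines(corpus$deleted, file.path(dir, "deleted.txt"))
  utils::write.table(corpus$dict$pt_to_soc, file.path(dir, "pt_soc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(corpus$dict$drug_synonyms, file.path(dir, "drug_synonyms.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- corpus$truth
  truth$planted <- as.list(truth$planted)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @return list with `tables` (per-table data.frames, quarters concatenated),
#'   `deleted` (CASEIDs) and `dict` (a [dictionary_tables()] object).
#' @export
read_corpus_dir <- function(dir) {
  qdirs <- list.dirs(dir, recursive = FALSE)
  tables <- stats::setNames(vector("list", length(FAERS_TABLES)), FAERS_TABLES)
  for (qd in qdirs) {
    for (t in FAERS_TABLES) {
      f <- file.path(qd, paste0(t, ".txt"))
      if (file.exists(f)) {
        tables[[t]] <- rbind(tables[[t]], read_faers_table(f, t, basename(qd)))
      }
    }
  }
  deleted <- if (file.exists(file.path(dir, "deleted.txt"))) {
    read_deleted_list(file.path(dir, "deleted.txt"))
  } else character(0)
  dict <- dictionary_tables(file.path(dir, "pt_soc.tsv"),
                            file.path(dir, "drug_synonyms.tsv"))
  list(tables = tables, deleted = deleted, dict = dict)
}

#' Concatenate the quarterly tables of an in-memory corpus
#'
#' @param corpus A [generate_corpus()] result.
#' @return Named list of per-table data.frames (all quarters row-bound).
#' @export
corpus_tables <- function(corpus) {
  out <- list()
  for (t in FAERS_TABLES) {
    out[[t]] <- do.call(rbind, lapply(corpus$quarters, `[[`, t))
    row.names(out[[t]]) <- NULL
  }
  out
}
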