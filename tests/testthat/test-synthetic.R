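small_spec <- function(...) {
  planted_signal_spec(n_target = 150, n_background = 1500, ...)
}

test_that("spec validation rejects inconsistent parameters before any output", {
  expect_error(planted_signal_spec(duplicate_fraction = 1.2), "\\[0, 1\\]")
  expect_error(planted_signal_spec(tto_shape = -1), "positive")
  expect_error(planted_signal_spec(
    demographic_mix = modifyList(faersignal:::default_demographic_mix(),
                                 list(sex = c(F = 0.6, M = 0.6)))),
    "summing to 1")
  expect_error(planted_signal_spec(
    associations = data.frame(pt = "nausea", rr = 10, baseline = 0.01)),
    "disjoint")
})

test_that("the corpus is a deterministic function of the spec", {
  s <- small_spec(seed = 5)
  c1 <- generate_corpus(s)
  c2 <- generate_corpus(s)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(c1, d1); write_corpus(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  c3 <- generate_corpus(small_spec(seed = 6))
  expect_false(identical(c1$quarters, c3$quarters))
})

test_that("without contamination the case count is conserved exactly", {
  s <- small_spec(duplicate_fraction = 0, deleted_fraction = 0, seed = 2)
  corpus <- generate_corpus(s)
  tabs <- corpus_tables(corpus)
  expect_equal(nrow(tabs$DEMO), 150 + 1500)
  expect_equal(length(unique(tabs$DEMO$caseid)), 150 + 1500)
  expect_equal(length(corpus$deleted), 0L)
  # every report carries at least one reaction
  expect_true(all(tabs$DEMO$primaryid %in% tabs$REAC$primaryid))
})

test_that("contamination bookkeeping matches the cleaning counts", {
  s <- small_spec(duplicate_fraction = 0.08, deleted_fraction = 0.02, seed = 3)
  corpus <- generate_corpus(s)
  tabs <- corpus_tables(corpus)
  dict <- dictionary_tables(corpus$dict$pt_to_soc, corpus$dict$drug_synonyms)
  cl <- clean_faers(tabs, corpus$deleted, dict)
  expect_equal(cl$counts$duplicates_removed, length(corpus$truth$duplicate_caseids))
  expect_equal(cl$counts$duplicates_removed, round(0.08 * 1650))
  expect_equal(cl$counts$deleted_removed, length(corpus$truth$deleted_caseids))
  expect_equal(cl$counts$reports_out, 1650)
  # the retained version of a duplicated case is the later one
  dd <- deduplicate_reports(tabs$DEMO)
  expect_true(all(endsWith(dd$kept$primaryid[dd$kept$caseid %in%
                                               corpus$truth$duplicate_caseids], "2")))
})

test_that("written corpora read back to the same analysis input", {
  s <- small_spec(seed = 9)
  corpus <- generate_corpus(s)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  back <- read_corpus_dir(dir)
  mem <- corpus_tables(corpus)
  for (t in names(mem)) {
    a <- mem[[t]]; b <- back$tables[[t]]
    a <- a[order(a$primaryid), , drop = FALSE]
    b <- b[order(b$primaryid), , drop = FALSE]
    row.names(a) <- row.names(b) <- NULL
    attributes(b) <- attributes(b)[c("names", "class", "row.names")]
    expect_equal(a, b)
  }
  expect_identical(sort(back$deleted), sort(corpus$deleted))
})

test_that("null associations give calibrated reporting odds ratios", {
  # a planted rate of 1 means no disproportionality: the log-ROR of the
  # planted PT should be centred at zero across seeds; the baseline is set
  # high enough that the odds-ratio estimator's own small-count bias is well
  # below the Monte-Carlo resolution of the check
  assoc <- data.frame(pt = "planted pt", rr = 1, baseline = 0.08)
  n_t <- 400; n_b <- 1500
  lrors <- vapply(1:200, function(seed) {
    s <- planted_signal_spec(associations = assoc, n_target = n_t,
                             n_background = n_b, duplicate_fraction = 0,
                             deleted_fraction = 0, seed = seed)
    corpus <- generate_corpus(s)
    reac <- corpus_tables(corpus)$REAC
    a <- sum(reac$pt == "planted pt" & reac$caseid %in% corpus$truth$target_caseids)
    cc <- sum(reac$pt == "planted pt" & !reac$caseid %in% corpus$truth$target_caseids)
    log(ror_stats(a, n_t - a, cc, n_b - cc)$ror)
  }, numeric(1))
  se <- sd(lrors) / sqrt(length(lrors))
  expect_lt(abs(mean(lrors)), 3 * se)
})

test_that("generated onset times refit to the planted Weibull parameters", {
  s <- planted_signal_spec(n_target = 400, n_background = 100,
                           missing_date_fraction = 0, duplicate_fraction = 0,
                           deleted_fraction = 0, seed = 11)
  corpus <- generate_corpus(s)
  tabs <- corpus_tables(corpus)
  dict <- dictionary_tables(corpus$dict$pt_to_soc, corpus$dict$drug_synonyms)
  cl <- clean_faers(tabs, corpus$deleted, dict)
  pop <- select_target_population(cl$cases, "pralatrexate")
  tto <- compute_tto(pop$target)
  expect_gte(nrow(tto$records), 300)
  fit <- fit_weibull(tto$records)
  se_beta <- (fit$beta_ci[2] - fit$beta_ci[1]) / (2 * 1.96)
  se_alpha <- (fit$alpha_ci[2] - fit$alpha_ci[1]) / (2 * 1.96)
  expect_lt(abs(fit$beta - 0.63), 3 * se_beta)
  expect_lt(abs(fit$alpha - 45.74), 3 * se_alpha)
})

test_that("planted relative rates surface as consensus signals end-to-end", {
  s <- planted_signal_spec(
    associations = data.frame(pt = "planted pt", rr = 10, baseline = 0.01),
    n_target = 2000, n_background = 20000, seed = 17
  )
  corpus <- generate_corpus(s)
  tabs <- corpus_tables(corpus)
  dict <- dictionary_tables(corpus$dict$pt_to_soc, corpus$dict$drug_synonyms)
  cl <- clean_faers(tabs, corpus$deleted, dict)
  pop <- select_target_population(cl$cases, "pralatrexate")
  ct <- build_contingency_tables(pop$target, pop$background)
  sig <- detect_signals(ct, n_draws = 2e4, seed = 1)
  expect_true(sig$consensus[sig$pt == "planted pt"])
  # ROR point estimate consistent with the planted rate
  row <- sig[sig$pt == "planted pt", ]
  expect_gt(row$ror_hi, 10 * 0.6)
  expect_lt(row$ror_lo, 10 * 1.6)
})
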