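SUBGROUP_AXES <- list(
  sex = c("F", "M"),
  age_group = c("<18", "18-44", "45-64", ">=65", "<65"),
  report_type = c("serious", "non-serious")
)

# report ids belonging to a stratum; reports with unknown sex/age are
# excluded from the respective axes (not imputed)
stratum_ids <- function(cases, axis, level) {
  r <- cases$reports
  switch(axis,
    sex = r$primaryid[r$sex == level],
    age_group = if (level == "<65") {
      r$primaryid[r$age_group %in% c("<18", "18-44", "45-64")]
    } else {
      r$primaryid[r$age_group == level]
    },
    report_type = r$primaryid[r$serious == (level == "serious")],
    stop("unknown subgroup axis: ", axis)
  )
}

#' ROR-based signal screening within one demographic stratum
#'
#' Restricts both the target and background populations to the stratum
#' (sex F/M; age groups including the binary `<65` split; serious vs
#' non-serious report type), rebuilds the per-PT contingency tables there,
#' and screens with the ROR criterion alone (a >= 3 and CI lower bound > 1),
#' as subgroup analyses conventionally do. Results are ranked by descending
#' frequency `a` (ties by PT) for top-k reporting.
#'
#' @param target,background `faers_cases` objects.
#' @param axis One of `"sex"`, `"age_group"`, `"report_type"`.
#' @param level Stratum label valid for the axis.
#' @param min_count Minimum target count `a` (default 3).
#' @return data.frame of per-PT ROR results with `flag_ror`; zero rows (with
#'   a warning) when the stratum holds no target reports.
#' @export
stratified_signals <- function(target, background, axis, level, min_count = 3) {
  axis <- match.arg(axis, names(SUBGROUP_AXES))
  if (!level %in% SUBGROUP_AXES[[axis]]) {
    stop("level '", level, "' not valid for axis '", axis, "'")
  }
  t_sub <- subset_cases(target, stratum_ids(target, axis, level))
  b_sub <- subset_cases(background, stratum_ids(background, axis, level))
  if (n_reports(t_sub) == 0L || n_reports(b_sub) == 0L) {
    warning("empty stratum ", axis, "=", level)
    return(data.frame(pt = character(0), soc = character(0),
                      a = integer(0), b = integer(0), c = integer(0), d = integer(0),
                      ror = numeric(0), ror_lo = numeric(0), ror_hi = numeric(0),
                      flag_ror = logical(0)))
  }
  tab <- build_contingency_tables(t_sub, b_sub)
  tab <- tab[tab$a >= min_count, , drop = FALSE]
  res <- cbind(tab, ror_stats(tab$a, tab$b, tab$c, tab$d))
  res <- res[order(-res$a, res$pt), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Sex-difference disproportionality within the target-drug population
#'
#' For each PT, forms the 2x2 table (female with PT, female other PTs, male
#' with PT, male other PTs) over target-drug reports of known sex, computes
#' the ROR with its 95% CI (Haldane correction for zero cells), labels the
#' direction (*female-biased*: ROR > 1 with CI lower > 1; *male-biased*:
#' ROR < 1 with CI upper < 1; otherwise *none*), attaches a p-value
#' (Fisher's exact test when any expected cell is below 5, else the
#' chi-square test) and a Benjamini-Hochberg FDR q-value across the tested
#' PTs. Volcano-ready columns `log2_ror` and `neglog10_p` are included.
#'
#' @param target A `faers_cases` object restricted to the target drug.
#' @param pts Optional character vector of PTs to test (default: every PT
#'   observed in at least one report of either sex). PTs absent from both
#'   sexes are skipped.
#' @return data.frame, one row per tested PT.
#' @export
sex_difference <- function(target, pts = NULL) {
  r <- target$reports
  f_ids <- r$primaryid[r$sex == "F"]
  m_ids <- r$primaryid[r$sex == "M"]
  if (length(f_ids) == 0L || length(m_ids) == 0L) {
    stop("both sexes must be present among target reports")
  }
  ev <- target$events[target$events$primaryid %in% c(f_ids, m_ids), , drop = FALSE]
  if (is.null(pts)) pts <- sort(unique(ev$pt))
  tab_f <- table(ev$pt[ev$primaryid %in% f_ids])
  tab_m <- table(ev$pt[ev$primaryid %in% m_ids])
  a <- as.integer(tab_f[pts]); a[is.na(a)] <- 0L
  cc <- as.integer(tab_m[pts]); cc[is.na(cc)] <- 0L
  present <- (a + cc) > 0L
  pts <- pts[present]; a <- a[present]; cc <- cc[present]
  b <- length(f_ids) - a
  d <- length(m_ids) - cc
  rs <- ror_stats(a, b, cc, d)
  direction <- rep("none", length(pts))
  direction[rs$ror > 1 & rs$ror_lo > 1] <- "female-biased"
  direction[rs$ror < 1 & rs$ror_hi < 1] <- "male-biased"
  p <- vapply(seq_along(pts), function(i) {
    m <- matrix(c(a[i], b[i], cc[i], d[i]), 2L, byrow = TRUE)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expd < 5)) {
      stats::fisher.test(m)$p.value
    } else {
      suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
    }
  }, numeric(1L))
  out <- data.frame(pt = pts, a_female = a, b_female = b, a_male = cc, b_male = d,
                    ror = rs$ror, ror_lo = rs$ror_lo, ror_hi = rs$ror_hi,
                    direction = direction, p_value = p,
                    fdr_q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$log2_ror <- log2(out$ror)
  out$neglog10_p <- -log10(out$p_value)
  row.names(out) <- NULL
  out
}
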