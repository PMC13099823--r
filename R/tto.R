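TTO_BUCKET_LABELS <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                       "151-180", "181-360", ">360")

#' Bucket time-to-onset values into the conventional occurrence-time strata
#'
#' Buckets are closed on the right: 0-30 includes day 30, 31-60 includes day
#' 60, and so on; everything above 360 days falls in `>360`.
#'
#' @param tto_days Non-negative numeric onset times in days.
#' @return Character vector of bucket labels.
#' @export
tto_bucket <- function(tto_days) {
  cuts <- c(-Inf, 30, 60, 90, 120, 150, 180, 360, Inf)
  as.character(cut(tto_days, cuts, labels = TTO_BUCKET_LABELS, right = TRUE))
}

#' Compute report-level time to onset with exclusion bookkeeping
#'
#' Time to onset is the interval in days from therapy initiation (earliest
#' complete primary-suspect therapy start) to adverse-event onset (the
#' report's event date). Reports are excluded — tallied, not dropped silently
#' — when either date is missing, when a date is only partially known
#' (year or year-month), or when the event precedes therapy initiation.
#'
#' @param cases A `faers_cases` object (or its `reports` data.frame).
#' @return A list: `records` (data.frame `primaryid`, `tto_days`, `bucket`)
#'   and `excluded`, a named integer vector over reasons
#'   `missing_event_date`, `missing_start_date`, `incomplete_date`,
#'   `negative`.
#' @export
compute_tto <- function(cases) {
  rep_df <- if (inherits(cases, "faers_cases")) cases$reports else cases
  ev_st <- rep_df$event_date_status
  th_st <- rep_df$therapy_start_status
  reason <- rep(NA_character_, nrow(rep_df))
  reason[ev_st == "incomplete" | th_st == "incomplete"] <- "incomplete_date"
  reason[is.na(reason) & ev_st == "missing"] <- "missing_event_date"
  reason[is.na(reason) & th_st == "missing"] <- "missing_start_date"
  ok <- is.na(reason)
  tto <- as.numeric(rep_df$event_date[ok] - rep_df$therapy_start[ok])
  neg <- tto < 0
  reason[which(ok)[neg]] <- "negative"
  records <- data.frame(primaryid = rep_df$primaryid[ok][!neg],
                        tto_days = tto[!neg],
                        bucket = tto_bucket(tto[!neg]),
                        stringsAsFactors = FALSE)
  reasons <- c("missing_event_date", "missing_start_date", "incomplete_date", "negative")
  excluded <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1L))
  list(records = records, excluded = excluded)
}

#' Bucket histogram of onset times
#'
#' @param records TTO records data.frame from [compute_tto()], or a numeric
#'   vector of onset days.
#' @return Named integer vector over the eight buckets (sums to `n`).
#' @export
bucket_distribution <- function(records) {
  b <- if (is.data.frame(records)) records$bucket else tto_bucket(records)
  counts <- table(factor(b, levels = TTO_BUCKET_LABELS))
  stats::setNames(as.integer(counts), TTO_BUCKET_LABELS)
}

#' Fit a Weibull onset-time model and classify the failure type
#'
#' Maximum-likelihood fit of the two-parameter Weibull density
#' `f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)` to observed
#' onset times. 95% Wald confidence intervals are computed on the log
#' parameters from the observed information and back-transformed, so the
#' bounds respect positivity. The failure type follows the shape parameter's
#' CI against 1: *early* (hazard decreasing) when the upper bound is below 1,
#' *wear-out* (hazard increasing) when the lower bound exceeds 1, otherwise
#' *random*.
#'
#' Zero-day onsets (event on the therapy start date) are shifted to 0.5 days
#' for the likelihood only; the empirical median and IQR use the raw values.
#'
#' @param records TTO records from [compute_tto()] or a numeric vector of
#'   onset days (>= 0).
#' @return An object of class `weibull_fit`: list with `n`, `alpha`,
#'   `alpha_ci`, `beta`, `beta_ci`, `tto_median`, `tto_iqr`, `failure_type`,
#'   `loglik`.
#' @export
fit_weibull <- function(records) {
  t_raw <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  t_raw <- t_raw[!is.na(t_raw)]
  n <- length(t_raw)
  if (n < 10L) stop("need at least 10 onset times to fit (got ", n, ")")
  if (length(unique(t_raw)) == 1L) {
    stop("degenerate likelihood: all onset times identical")
  }
  t_fit <- ifelse(t_raw == 0, 0.5, t_raw)
  fd <- fitdistrplus::fitdist(t_fit, "weibull",
                              control = list(reltol = 1e-12, maxit = 2000))
  # polish to the exact MLE: root of the profile score in the shape, with the
  # scale then available in closed form
  lt <- log(t_fit)
  u <- t_fit / exp(mean(lt)) # geometric-mean scaling for numerical stability
  lu <- log(u)
  score <- function(sh) 1 / sh - sum(u^sh * lu) / sum(u^sh)
  b0 <- unname(fd$estimate["shape"])
  lo <- b0 / 2; hi <- b0 * 2
  while (score(lo) < 0) lo <- lo / 2
  while (score(hi) > 0) hi <- hi * 2
  beta <- stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
  alpha <- exp(mean(lt)) * mean(u^beta)^(1 / beta)
  se <- fd$sd
  # Wald on log scale: sd(log theta) = se(theta)/theta (delta method)
  ci <- function(est, se_nat) {
    s <- se_nat / est
    exp(log(est) + c(-1, 1) * stats::qnorm(0.975) * s)
  }
  beta_ci <- ci(beta, unname(se["shape"]))
  alpha_ci <- ci(alpha, unname(se["scale"]))
  failure_type <- if (beta_ci[2] < 1) "early" else if (beta_ci[1] > 1) "wear-out" else "random"
  q <- stats::quantile(t_raw, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(n = n, alpha = alpha, alpha_ci = alpha_ci,
                 beta = beta, beta_ci = beta_ci,
                 tto_median = q[2], tto_iqr = c(q[1], q[3]),
                 failure_type = failure_type,
                 loglik = sum(stats::dweibull(t_fit, beta, alpha, log = TRUE))),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Weibull time-to-onset fit (n = %d)\n",
    "  median (IQR): %.2f (%.2f, %.2f) days\n",
    "  scale alpha : %.2f  [%.2f, %.2f]\n",
    "  shape beta  : %.3f [%.3f, %.3f]\n",
    "  failure type: %s\n"),
    x$n, x$tto_median, x$tto_iqr[1], x$tto_iqr[2],
    x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' One-row summary table of a Weibull onset fit
#'
#' @param fit A `weibull_fit`.
#' @param drug Optional drug label for the first column.
#' @return data.frame mirroring the conventional onset-analysis table layout:
#'   n, median (IQR), scale with CI, shape with CI, failure type.
#' @export
weibull_summary_table <- function(fit, drug = "target") {
  data.frame(drug = drug, n = fit$n,
             tto_median = fit$tto_median,
             tto_q1 = fit$tto_iqr[1], tto_q3 = fit$tto_iqr[2],
             alpha = fit$alpha, alpha_lo = fit$alpha_ci[1], alpha_hi = fit$alpha_ci[2],
             beta = fit$beta, beta_lo = fit$beta_ci[1], beta_hi = fit$beta_ci[2],
             failure_type = fit$failure_type,
             stringsAsFactors = FALSE)
}
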