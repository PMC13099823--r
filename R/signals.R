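#' Build per-PT 2x2 contingency tables against the background population
#'
#' For each preferred term (PT) observed in either population, counts at the
#' report level (a report contributes at most one to a cell for a given PT):
#' `a` target reports with the PT, `b` target reports without it, `c`
#' background reports with it, `d` background reports without it. Margins
#' `a + b` (target reports) and `c + d` (background reports) are identical
#' across all PTs.
#'
#' @param target,background `faers_cases` objects (target must be non-empty).
#' @return A data.frame with columns `pt`, `soc`, `a`, `b`, `c`, `d`.
#' @export
build_contingency_tables <- function(target, background) {
  n_t <- n_reports(target)
  n_b <- n_reports(background)
  if (n_t == 0L) stop("no target reports")
  if (n_b == 0L) stop("no background reports")
  tab_t <- table(target$events$pt)
  tab_b <- table(background$events$pt)
  pts <- sort(union(names(tab_t), names(tab_b)))
  a <- as.integer(tab_t[pts]); a[is.na(a)] <- 0L
  cc <- as.integer(tab_b[pts]); cc[is.na(cc)] <- 0L
  soc_map <- c(stats::setNames(target$events$soc, target$events$pt),
               stats::setNames(background$events$soc, background$events$pt))
  data.frame(pt = pts,
             soc = unname(soc_map[pts]),
             a = a, b = n_t - a, c = cc, d = n_b - cc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Haldane-Anscombe: add 0.5 to every cell of tables with any zero cell.
# Applied to ROR/PRR/chi-square only; the Bayesian methods handle zeros
# natively.
continuity_correct <- function(a, b, c, d) {
  z <- (a == 0 | b == 0 | c == 0 | d == 0)
  list(a = a + 0.5 * z, b = b + 0.5 * z, c = c + 0.5 * z, d = d + 0.5 * z)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d)/(b c)`, with Wald CI
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero,
#' 0.5 is added to every cell (Haldane-Anscombe) before computing. The signal
#' flag requires `a >= 3` and a CI lower bound `> 1`.
#'
#' @param a,b,c,d Vectors of 2x2 cell counts (target-with-PT, target-other,
#'   background-with-PT, background-other).
#' @return data.frame with `ror`, `ror_lo`, `ror_hi`, `flag_ror`.
#' @export
ror_stats <- function(a, b, c, d) {
  cc <- continuity_correct(a, b, c, d)
  ror <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  data.frame(ror = ror, ror_lo = lo, ror_hi = hi,
             flag_ror = (a >= 3) & (lo > 1))
}

# Yates-corrected chi-square of a 2x2 table, closed form
yates_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  stat[!is.finite(stat)] <- 0
  stat
}

#' Proportional reporting ratio with MHRA-style criteria
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the accompanying chi-square uses the Yates
#' continuity correction (configurable off). Flag: `a >= 3`, `PRR >= 2`,
#' `chi2 >= 4` (boundaries inclusive). Zero cells receive the same 0.5
#' correction as [ror_stats()].
#'
#' @param a,b,c,d 2x2 cell counts.
#' @param yates Apply the Yates correction to the chi-square (default TRUE).
#' @return data.frame with `prr`, `chi2`, `flag_prr`.
#' @export
prr_stats <- function(a, b, c, d, yates = TRUE) {
  cc <- continuity_correct(a, b, c, d)
  prr <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  chi2 <- if (yates) {
    yates_chi2(cc$a, cc$b, cc$c, cc$d)
  } else {
    n <- cc$a + cc$b + cc$c + cc$d
    n * (cc$a * cc$d - cc$b * cc$c)^2 /
      ((cc$a + cc$b) * (cc$c + cc$d) * (cc$a + cc$c) * (cc$b + cc$d))
  }
  data.frame(prr = prr, chi2 = chi2,
             flag_prr = (a >= 3) & (prr >= 2) & (chi2 >= 4))
}

#' BCPNN information component by posterior simulation
#'
#' The Bayesian confidence propagation neural network information component
#' `IC = log2 p(drug, event) / (p(drug) p(event))` under the original
#' unit-information beta priors. The normative computation is Monte-Carlo:
#' independent posterior draws of the joint cell probability and the two
#' margins, `IC` draws formed per sample; the point estimate is the posterior
#' expectation (or median), `ic025` the 2.5th percentile. A closed-form
#' approximation (`method = "closed"`) uses the exact digamma/trigamma
#' moments of the log-beta posteriors with a normal quantile for `ic025`.
#'
#' Priors: margins `Beta(1, 1)`; joint `Beta(1, 1/(E[p_x] E[p_y]) - 1)` so the
#' prior IC is centred at zero, with `E[p_x] = (a+b+1)/(N+2)`,
#' `E[p_y] = (a+c+1)/(N+2)`.
#'
#' @param a,b,c,d 2x2 cell counts.
#' @param n_draws Monte-Carlo sample size (>= 10000; default 1e5).
#' @param seed Integer seed making the draw deterministic.
#' @param point `"expectation"` (default) or `"median"`.
#' @param method `"mc"` (normative) or `"closed"`.
#' @return data.frame with `ic`, `ic025`, `flag_ic` (`ic025 > 0`).
#' @export
bcpnn_ic <- function(a, b, c, d, n_draws = 1e5, seed = 20251,
                     point = c("expectation", "median"), method = c("mc", "closed")) {
  point <- match.arg(point)
  method <- match.arg(method)
  n <- a + b + c + d
  if (any(n == 0)) stop("degenerate table: N = 0")
  n1. <- a + b
  n.1 <- a + c
  e_px <- (n1. + 1) / (n + 2)
  e_py <- (n.1 + 1) / (n + 2)
  b11 <- 1 / (e_px * e_py) - 1
  if (method == "mc") {
    if (n_draws < 1e4) stop("n_draws must be at least 10000")
    k <- length(a)
    ic <- ic025 <- numeric(k)
    for (i in seq_len(k)) {
      set.seed(seed + i - 1L)
      p_x <- stats::rbeta(n_draws, 1 + n1.[i], 1 + n[i] - n1.[i])
      p_y <- stats::rbeta(n_draws, 1 + n.1[i], 1 + n[i] - n.1[i])
      p_xy <- stats::rbeta(n_draws, 1 + a[i], b11[i] + n[i] - a[i])
      draws <- log2(p_xy / (p_x * p_y))
      ic[i] <- if (point == "expectation") mean(draws) else stats::median(draws)
      ic025[i] <- stats::quantile(draws, 0.025, names = FALSE)
    }
  } else {
    # cumulants of ln Beta(al, be) are polygamma differences; the IC is a
    # sum/difference of three independent log-betas, so cumulants add
    k1 <- function(al, be) digamma(al) - digamma(al + be)
    k2 <- function(al, be) trigamma(al) - trigamma(al + be)
    k3 <- function(al, be) psigamma(al, 2) - psigamma(al + be, 2)
    pars <- list(j = cbind(1 + a, b11 + n - a),
                 x = cbind(1 + n1., 1 + n - n1.),
                 y = cbind(1 + n.1, 1 + n - n.1))
    mu <- (k1(pars$j[, 1], pars$j[, 2]) - k1(pars$x[, 1], pars$x[, 2]) -
             k1(pars$y[, 1], pars$y[, 2])) / log(2)
    v <- (k2(pars$j[, 1], pars$j[, 2]) + k2(pars$x[, 1], pars$x[, 2]) +
            k2(pars$y[, 1], pars$y[, 2])) / log(2)^2
    m3 <- (k3(pars$j[, 1], pars$j[, 2]) - k3(pars$x[, 1], pars$x[, 2]) -
             k3(pars$y[, 1], pars$y[, 2])) / log(2)^3
    sdv <- sqrt(v)
    skew <- m3 / sdv^3
    z <- stats::qnorm(0.025)
    # Cornish-Fisher second-order quantile, capturing the left skew at low
    # counts
    zq <- z + skew * (z^2 - 1) / 6
    ic <- mu
    ic025 <- mu + zq * sdv
  }
  data.frame(ic = ic, ic025 = ic025, flag_ic = ic025 > 0)
}

#' MGPS prior hyperparameters
#'
#' The multi-item gamma-Poisson shrinker places a two-component gamma mixture
#' prior on the relative reporting rate lambda. Defaults are the published
#' fit to FDA spontaneous-report data that FAERS disproportionality studies
#' conventionally reuse.
#'
#' @param alpha1,beta1 Shape/rate of the first gamma component.
#' @param alpha2,beta2 Shape/rate of the second component.
#' @param w Mixture weight of the first component, in (0, 1).
#' @return A named list of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mgps_prior parameters must be positive")
  }
  if (!is.finite(w) || w <= 0 || w >= 1) stop("mixture weight w must be in (0, 1)")
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w), class = "mgps_prior")
}

# posterior mixture for one table: component weights and gamma parameters
mgps_posterior <- function(a, E, prior) {
  # marginal likelihood of each component: negative binomial
  m1 <- stats::dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E))
  m2 <- stats::dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E))
  q1 <- prior$w * m1 / (prior$w * m1 + (1 - prior$w) * m2)
  list(q1 = q1,
       a1 = prior$alpha1 + a, b1 = prior$beta1 + E,
       a2 = prior$alpha2 + a, b2 = prior$beta2 + E)
}

#' Empirical-Bayes geometric mean (EBGM) and its 5th percentile (EB05)
#'
#' For observed count `a ~ Poisson(lambda E)` with baseline expectation
#' `E = (a+b)(a+c)/N`, the gamma-mixture prior is conjugate: the posterior is
#' again a two-gamma mixture with negative-binomial marginal weights.
#' `EBGM = 2^{E[log2 lambda | a]}` via the digamma identity; `EB05` is the
#' 5th percentile of the mixture posterior, found by monotone root-finding on
#' its CDF. Flag: `EB05 > 2`.
#'
#' @param a,b,c,d 2x2 cell counts.
#' @param prior An [mgps_prior()].
#' @return data.frame with `E`, `ebgm`, `eb05`, `flag_ebgm`.
#' @export
mgps_ebgm <- function(a, b, c, d, prior = mgps_prior()) {
  if (!inherits(prior, "mgps_prior")) prior <- do.call(mgps_prior, as.list(prior))
  n <- a + b + c + d
  E <- (a + b) * (a + c) / n
  if (any(E <= 0)) stop("expected count E must be positive for every table")
  post <- mgps_posterior(a, E, prior)
  elog <- post$q1 * (digamma(post$a1) - log(post$b1)) +
    (1 - post$q1) * (digamma(post$a2) - log(post$b2))
  ebgm <- 2^(elog / log(2))
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(q) {
      post$q1[i] * stats::pgamma(q, post$a1[i], rate = post$b1[i]) +
        (1 - post$q1[i]) * stats::pgamma(q, post$a2[i], rate = post$b2[i]) - 0.05
    }
    hi <- max(ebgm[i], 1)
    while (cdf(hi) < 0) hi <- hi * 2
    stats::uniroot(cdf, c(0, hi), tol = 1e-10)$root
  }, numeric(1L))
  data.frame(E = E, ebgm = ebgm, eb05 = eb05, flag_ebgm = eb05 > 2)
}

#' Estimate MGPS hyperparameters from the full table set
#'
#' Maximizes the marginal negative-binomial mixture likelihood of all
#' observed counts over the five hyperparameters (box-transformed to the
#' real line). Offered as an alternative to the conventional fixed prior.
#'
#' @param tables A contingency data.frame from [build_contingency_tables()].
#' @param init Starting [mgps_prior()].
#' @return An [mgps_prior()] with the fitted values.
#' @export
fit_mgps_prior <- function(tables, init = mgps_prior()) {
  a <- tables$a
  E <- (tables$a + tables$b) * (tables$a + tables$c) /
    (tables$a + tables$b + tables$c + tables$d)
  nll <- function(par) {
    p <- list(alpha1 = exp(par[1]), beta1 = exp(par[2]),
              alpha2 = exp(par[3]), beta2 = exp(par[4]),
              w = stats::plogis(par[5]))
    m1 <- stats::dnbinom(a, size = p$alpha1, prob = p$beta1 / (p$beta1 + E))
    m2 <- stats::dnbinom(a, size = p$alpha2, prob = p$beta2 / (p$beta2 + E))
    -sum(log(pmax(p$w * m1 + (1 - p$w) * m2, 1e-300)))
  }
  start <- c(log(init$alpha1), log(init$beta1), log(init$alpha2),
             log(init$beta2), stats::qlogis(init$w))
  fit <- stats::nlminb(start, nll)
  mgps_prior(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]),
             exp(fit$par[4]), stats::plogis(fit$par[5]))
}

#' Four-algorithm signal detection with the all-four consensus rule
#'
#' Runs ROR, PRR, BCPNN-IC and MGPS on every PT table with at least
#' `min_count` target reports, flags each statistic against its conventional
#' threshold (ROR: a >= 3 and CI lower > 1; PRR: a >= 3, PRR >= 2, chi2 >= 4;
#' IC025 > 0; EB05 > 2), and declares a *consensus* signal only when all four
#' flags hold. Results are ranked by descending ROR, ties broken by larger
#' `a` then PT alphabetically.
#'
#' @param tables Contingency data.frame from [build_contingency_tables()].
#' @param min_count Minimum `a` for a PT to be evaluated (default 3).
#' @param prior [mgps_prior()] (or `"fit"` to re-estimate from the data).
#' @param n_draws,seed BCPNN Monte-Carlo controls.
#' @param ic_method `"mc"` or `"closed"`, see [bcpnn_ic()].
#' @param yates Yates correction for the PRR chi-square.
#' @return A data.frame (one row per evaluated PT) with the table cells, all
#'   statistics, per-algorithm flags and `consensus`.
#' @export
detect_signals <- function(tables, min_count = 3, prior = mgps_prior(),
                           n_draws = 1e5, seed = 20251,
                           ic_method = c("mc", "closed"), yates = TRUE) {
  ic_method <- match.arg(ic_method)
  tab <- tables[tables$a >= min_count, , drop = FALSE]
  if (nrow(tab) == 0L) {
    out <- cbind(tables[0L, , drop = FALSE],
                 ror = numeric(0), ror_lo = numeric(0), ror_hi = numeric(0),
                 flag_ror = logical(0), prr = numeric(0), chi2 = numeric(0),
                 flag_prr = logical(0), ic = numeric(0), ic025 = numeric(0),
                 flag_ic = logical(0), E = numeric(0), ebgm = numeric(0),
                 eb05 = numeric(0), flag_ebgm = logical(0),
                 consensus = logical(0))
    return(out)
  }
  if (identical(prior, "fit")) prior <- fit_mgps_prior(tables)
  res <- cbind(
    tab,
    ror_stats(tab$a, tab$b, tab$c, tab$d),
    prr_stats(tab$a, tab$b, tab$c, tab$d, yates = yates),
    bcpnn_ic(tab$a, tab$b, tab$c, tab$d, n_draws = n_draws, seed = seed,
             method = ic_method),
    mgps_ebgm(tab$a, tab$b, tab$c, tab$d, prior = prior)
  )
  res$consensus <- res$flag_ror & res$flag_prr & res$flag_ic & res$flag_ebgm
  ord <- order(-res$ror, -res$a, res$pt)
  res <- res[ord, , drop = FALSE]
  row.names(res) <- NULL
  res
}
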