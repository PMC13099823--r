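# independent nested-loop counting oracle for contingency tables
oracle_tables <- function(target, background) {
  pts <- sort(unique(c(target$events$pt, background$events$pt)))
  do.call(rbind, lapply(pts, function(p) {
    has <- function(cases, id) any(cases$events$pt == p & cases$events$primaryid == id)
    a <- sum(vapply(target$reports$primaryid, function(id) has(target, id), logical(1)))
    cc <- sum(vapply(background$reports$primaryid, function(id) has(background, id), logical(1)))
    data.frame(pt = p, a = a, b = nrow(target$reports) - a,
               c = cc, d = nrow(background$reports) - cc)
  }))
}

test_that("contingency tables count at report level and match the oracle", {
  set.seed(11)
  n_t <- 8; n_b <- 12
  pts <- c("x", "y", "z")
  t_ev <- make_events(sprintf("p%04d", 1:n_t),
                      lapply(1:n_t, function(i) sample(pts, sample(0:3, 1))))
  # report p0001 lists PT x twice -> must contribute 1
  t_ev <- rbind(t_ev, data.frame(primaryid = "p0001", pt = "x", soc = "soc1"))
  b_ev <- make_events(sprintf("p%04d", 1:n_b),
                      lapply(1:n_b, function(i) sample(pts, sample(0:2, 1))))
  target <- make_cases(n_t, events = t_ev)
  background <- make_cases(n_b, events = b_ev)
  # per-report collapse happens at assembly; tables count distinct pairs
  target$events <- unique(target$events)
  background$events <- unique(background$events)
  got <- build_contingency_tables(target, background)
  orc <- oracle_tables(target, background)
  expect_equal(got[c("pt", "a", "b", "c", "d")], orc, ignore_attr = TRUE)
  # margin invariance across PTs
  expect_true(all(got$a + got$b == n_t))
  expect_true(all(got$c + got$d == n_b))
  expect_error(build_contingency_tables(make_cases(0), background), "no target")
})

test_that("single-PT direct counts are exact", {
  target <- make_cases(1, events = data.frame(primaryid = "p0001", pt = "x",
                                              soc = "s"))
  background <- make_cases(10, events = make_events(sprintf("p%04d", 1:10),
                                                    replicate(10, character(0))))
  background$events <- data.frame(primaryid = character(0), pt = character(0),
                                  soc = character(0))
  got <- build_contingency_tables(target, background)
  expect_equal(got$a, 1L)
  expect_equal(got$c, 0L)
})

test_that("ROR point estimate, CI and flag follow the Wald formula", {
  r <- ror_stats(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$ror_lo, exp(log(11) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$ror_hi, exp(log(11) + 1.96 * se), tolerance = 1e-12)
  expect_true(r$flag_ror)
  # independence
  expect_equal(ror_stats(1, 1, 1, 1)$ror, 1)
  expect_false(ror_stats(1, 1, 1, 1)$flag_ror)
  # minimum-count gate beats any effect size
  expect_false(ror_stats(2, 1, 1, 10000)$flag_ror)
  # zero cell: continuity correction, never Inf/NaN
  z <- ror_stats(5, 20, 0, 100)
  expect_true(is.finite(z$ror) && is.finite(z$ror_lo))
})

test_that("PRR and Yates chi-square match hand arithmetic and chisq.test", {
  p <- prr_stats(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  ref <- suppressWarnings(stats::chisq.test(matrix(c(10, 90, 100, 9900), 2,
                                                   byrow = TRUE),
                                            correct = TRUE))
  expect_equal(p$chi2, unname(ref$statistic), tolerance = 1e-9)
  # proportional table
  p0 <- prr_stats(10, 90, 100, 900)
  expect_equal(p0$prr, 1)
  expect_false(p0$flag_prr)
  # flags are inclusive at the thresholds
  tabs <- random_tables(100, seed = 5)
  pr <- prr_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(pr$flag_prr, tabs$a >= 3 & pr$prr >= 2 & pr$chi2 >= 4)
})

test_that("vectorized chi-square equals chisq.test on random tables", {
  tabs <- random_tables(50, seed = 9)
  got <- prr_stats(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  ref <- vapply(seq_len(50), function(i) {
    unname(suppressWarnings(stats::chisq.test(
      matrix(as.numeric(tabs[i, c("a", "b", "c", "d")]), 2, byrow = TRUE),
      correct = TRUE))$statistic)
  }, numeric(1))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("log ROR and log PRR agree for rare events on a large background", {
  tabs <- data.frame(a = c(5, 12, 30), b = c(995, 1988, 4970),
                     c = c(50, 110, 260), d = c(99950, 199890, 499740))
  ror <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  prr <- prr_stats(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  expect_true(all(abs(log(ror) - log(prr)) / abs(log(prr)) < 0.05))
})

test_that("information component is deterministic, centred at independence, and
          shrunk below zero without support", {
  r1 <- bcpnn_ic(100, 900, 1000, 9000, n_draws = 5e4, seed = 3)
  r2 <- bcpnn_ic(100, 900, 1000, 9000, n_draws = 5e4, seed = 3)
  expect_identical(r1, r2)
  expect_lt(abs(r1$ic), 0.05)
  expect_false(r1$flag_ic)
  r0 <- bcpnn_ic(0, 100, 100, 9800, n_draws = 1e4, seed = 3)
  expect_lt(r0$ic025, 0)
  expect_error(bcpnn_ic(0, 0, 0, 0), "N = 0")
  expect_error(bcpnn_ic(1, 1, 1, 1, n_draws = 100), "10000")
})

test_that("closed-form information component tracks the Monte-Carlo posterior", {
  # counts start at the minimum the detection rule ever evaluates (a >= 3)
  grid <- expand.grid(a = c(3, 5, 8, 20, 60),
                      c_mult = c(0.5, 1, 3, 10, 30),
                      n_t = c(200, 2000))
  a <- grid$a
  b <- grid$n_t - a
  cc <- pmax(1, round(a * grid$c_mult))
  d <- pmax(100, 20000 - cc)
  mc <- bcpnn_ic(a, b, cc, d, n_draws = 1e5, seed = 17)
  cf <- bcpnn_ic(a, b, cc, d, method = "closed")
  expect_equal(nrow(grid), 50)
  expect_lt(max(abs(mc$ic - cf$ic)), 0.05)
  expect_lt(max(abs(mc$ic025 - cf$ic025)), 0.05)
})

test_that("EBGM shrinks to the data in the large-count limit and to the prior at zero", {
  big <- mgps_ebgm(500, 500, 1000, 99000)
  E <- 1000 * 1500 / 101000
  expect_lt(abs(big$ebgm - 500 / E) / (500 / E), 0.05)
  null <- mgps_ebgm(0, 100, 500, 9400)
  expect_lt(null$ebgm, 1.2)
  expect_false(null$flag_ebgm)
  expect_error(mgps_prior(alpha1 = -1), "positive")
  expect_error(mgps_ebgm(0, 0, 0, 5), "positive")
})

test_that("EB05 from root-finding equals the Monte-Carlo posterior quantile", {
  tabs <- data.frame(a = c(2, 10, 40, 0), b = c(98, 490, 460, 100),
                     c = c(30, 200, 300, 50), d = c(9870, 49300, 9200, 9850))
  got <- mgps_ebgm(tabs$a, tabs$b, tabs$c, tabs$d)
  set.seed(99)
  for (i in seq_len(nrow(tabs))) {
    n <- sum(tabs[i, ])
    E <- (tabs$a[i] + tabs$b[i]) * (tabs$a[i] + tabs$c[i]) / n
    pr <- mgps_prior()
    m1 <- dnbinom(tabs$a[i], size = pr$alpha1, prob = pr$beta1 / (pr$beta1 + E))
    m2 <- dnbinom(tabs$a[i], size = pr$alpha2, prob = pr$beta2 / (pr$beta2 + E))
    q1 <- pr$w * m1 / (pr$w * m1 + (1 - pr$w) * m2)
    comp <- runif(1e6) < q1
    draws <- ifelse(comp,
                    rgamma(1e6, pr$alpha1 + tabs$a[i], rate = pr$beta1 + E),
                    rgamma(1e6, pr$alpha2 + tabs$a[i], rate = pr$beta2 + E))
    expect_lt(abs(got$eb05[i] - quantile(draws, 0.05, names = FALSE)), 0.01)
  }
})

test_that("hyperparameter re-estimation recovers a gamma-mixture generating prior", {
  set.seed(123)
  n <- 4000
  truth <- mgps_prior(0.3, 0.15, 2.5, 3, 0.4)
  E <- runif(n, 0.5, 30)
  comp <- runif(n) < truth$w
  lam <- ifelse(comp, rgamma(n, truth$alpha1, rate = truth$beta1),
                rgamma(n, truth$alpha2, rate = truth$beta2))
  a <- pmin(rpois(n, lam * E), 900L)
  # cells chosen so the baseline expectation (a+b)(a+c)/N reproduces E
  cc <- pmax(0, round(E * 1000) - a)
  tabs <- data.frame(a = a, b = 1000 - a, c = cc, d = 1e6 - 1000 - cc)
  fit <- fit_mgps_prior(tabs)
  # marginal likelihood at the fit is no worse than at the default start
  nll <- function(p) {
    Ehat <- (tabs$a + tabs$b) * (tabs$a + tabs$c) / (tabs$a + tabs$b + tabs$c + tabs$d)
    m1 <- dnbinom(tabs$a, size = p$alpha1, prob = p$beta1 / (p$beta1 + Ehat))
    m2 <- dnbinom(tabs$a, size = p$alpha2, prob = p$beta2 / (p$beta2 + Ehat))
    -sum(log(p$w * m1 + (1 - p$w) * m2))
  }
  expect_lte(nll(fit), nll(mgps_prior()) + 1e-6)
  expect_lte(nll(fit), nll(truth) + 1e-6)
})

test_that("consensus is the conjunction of the four flags, ranked by descending ROR", {
  # strong joint signal, then a PT passing three of four (EB05 below 2)
  tabs <- data.frame(
    pt = c("strong", "weakbayes", "null"), soc = "s",
    a = c(40, 30, 10), b = c(460, 470, 490),
    c = c(100, 2400, 400), d = c(99900, 97600, 19600)
  )
  sig <- detect_signals(tabs, n_draws = 1e4, seed = 2)
  expect_equal(sig$pt[1], "strong")
  expect_true(sig$consensus[sig$pt == "strong"])
  wb <- sig[sig$pt == "weakbayes", ]
  expect_true(wb$flag_ror && wb$flag_prr)
  expect_false(wb$consensus)
  expect_false(sig$consensus[sig$pt == "null"])
  expect_equal(sig$ror, sort(sig$ror, decreasing = TRUE))
  # minimum-count filter and empty input
  tabs2 <- tabs; tabs2$a <- c(2, 2, 2); tabs2$b <- c(498, 498, 498)
  expect_equal(nrow(detect_signals(tabs2, n_draws = 1e4)), 0L)
})

test_that("ranking ties break by larger count then term order", {
  tabs <- data.frame(pt = c("zeta", "alpha", "beta"), soc = "s",
                     a = c(10, 10, 20), b = c(90, 90, 180),
                     c = c(10, 10, 20), d = c(990, 990, 1980))
  sig <- detect_signals(tabs, n_draws = 1e4, seed = 1)
  expect_equal(sig$pt, c("beta", "alpha", "zeta"))
})
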