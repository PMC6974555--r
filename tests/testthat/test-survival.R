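# Brute-force product-limit estimator over risk sets.
km_brute <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    d <- sum(times == ut[k] & events == 1)
    n <- sum(times >= ut[k])
    s <- s * (1 - d / n)
    out[k] <- s
  }
  tibble::tibble(time = ut, survival = out)
}

test_that("Kaplan-Meier matches the hand product-limit computation", {
  d <- tibble::tibble(t = c(1, 2, 3), e = c(1, 1, 0))
  km <- km_estimate(d, t, e)
  curve <- tidy(km)
  # S(2) = (2/3) * (1/2) = 1/3
  expect_equal(curve$survival[curve$time == 2], 1 / 3, tolerance = 1e-12)

  one <- km_estimate(tibble::tibble(t = 1, e = 1), t, e)
  expect_equal(tidy(one)$survival, 0)

  none <- km_estimate(tibble::tibble(t = c(2, 4, 5), e = c(0, 0, 0)), t, e)
  expect_true(all(tidy(none)$survival == 1))
  expect_equal(mortality_at(none, 5)$mortality_pct, 0)
})

test_that("KM equals brute force on random censored samples", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    t <- round(rexp(n, 0.3), 3)
    e <- rbinom(n, 1, 0.7)
    if (!sum(e)) e[1] <- 1
    km <- tidy(km_estimate(tibble::tibble(t, e), t, e))
    bf <- km_brute(t, e)
    at_events <- km[km$n_event > 0, ]
    expect_equal(at_events$survival, bf$survival, tolerance = 1e-12)
  }
})

test_that("KM curves are monotone with CI bounds bracketing the estimate", {
  set.seed(3)
  d <- tibble::tibble(t = rexp(300, 0.2), e = rbinom(300, 1, 0.6))
  curve <- tidy(km_estimate(d, t, e))
  expect_true(all(diff(curve$survival) <= 0))
  expect_true(all(curve$ci_low <= curve$survival + 1e-12))
  expect_true(all(curve$ci_high >= curve$survival - 1e-12))
  expect_true(all(curve$ci_low >= 0 & curve$ci_high <= 1))
})

test_that("log-rank is null on identical groups and matches hand O-E", {
  d <- tibble::tibble(t = rep(c(1, 2, 3, 4), 2), e = rep(c(1, 1, 0, 1), 2),
                      g = rep(c("a", "b"), each = 4))
  lr <- logrank_test(d, t, e, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)

  # 6-subject example, hand computation over event times
  d2 <- tibble::tibble(t = c(1, 2, 4, 3, 5, 6),
                       e = c(1, 1, 1, 1, 0, 1),
                       g = rep(c("a", "b"), each = 3))
  # risk sets: t=1 (3a,3b) event a; t=2 (2a,3b) event a; t=3 (1a,3b) event b;
  # t=4 (1a,2b) event a; t=6 (0a,1b) event b
  o_a <- 3
  e_a <- 3 / 6 + 2 / 5 + 1 / 4 + 1 / 3 + 0
  v <- (3 * 3) / 36 + (2 * 3) / 25 + (1 * 3) / 16 + (1 * 2) / 9 + 0
  want <- (o_a - e_a)^2 / v
  got <- logrank_test(d2, t, e, g)
  expect_equal(got$chi2, want, tolerance = 1e-9)
  expect_equal(got$p_value, pchisq(want, 1, lower.tail = FALSE))
})

test_that("log-rank separates strongly different exponential groups", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    d <- tibble::tibble(
      t = pmin(c(rexp(200, 0.1), rexp(200, 0.4)), 5),
      e = as.integer(t < 5),
      g = rep(c("lo", "hi"), each = 200)
    )
    d$t <- pmax(d$t, 1e-6)
    if (logrank_test(d, t, e, g)$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 49)
})

test_that("Cox recovers a known rate ratio and is null when unlinked", {
  set.seed(31)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.15 * 2^x)
  e <- as.integer(t <= 5)
  d <- tibble::tibble(t = pmin(t, 5), e = e, x = x)
  fit <- cox_fit(d, t, e, "x")
  hr <- tidy(fit)$hazard_ratio
  expect_gte(hr, 1.8)
  expect_lte(hr, 2.2)

  # permuted covariate: HR close to 1
  d$x <- sample(d$x)
  hr0 <- tidy(cox_fit(d, t, e, "x"))
  expect_gt(hr0$ci_high, 1 - 1e-9)
  expect_lt(abs(hr0$estimate), 0.2)
})

test_that("Cox rejects degenerate designs", {
  d <- tibble::tibble(t = rexp(50, 0.5), e = rep(1L, 50), x = 1)
  expect_error(cox_fit(d, t, e, "x"), "constant")
  d2 <- tibble::tibble(t = rexp(50, 0.5), e = c(1L, rep(0L, 49)),
                       x = rnorm(50), y = rnorm(50))
  expect_error(cox_fit(d2, t, e, c("x", "y")), "too few events")
  expect_error(cox_fit(d2, t, e, "missing_col"), "missing covariate")
})

test_that("Cox score test agrees with log-rank on a binary covariate", {
  set.seed(17)
  n <- 120
  t <- round(rexp(n, 0.2), 6)  # continuous: no ties
  d <- tibble::tibble(t = t, e = rbinom(n, 1, 0.8), x = rep(0:1, n / 2))
  fit <- cox_fit(d, t, e, "x")
  sc <- summary(fit$fit)$sctest
  lr <- logrank_test(d, t, e, x)
  expect_equal(unname(sc["test"]), lr$chi2, tolerance = 1e-6)
  expect_equal(unname(sc["pvalue"]), lr$p_value, tolerance = 1e-6)
})

test_that("the threshold scan is flat under the null and tracks a planted effect", {
  set.seed(23)
  n <- 600
  cvhr_min <- runif(n, 0, 300)
  # null: outcome independent of cvhr
  d0 <- tibble::tibble(cvhr = cvhr_min, t = pmin(rexp(n, 0.05), 5))
  d0$e <- as.integer(d0$t < 5)
  scan0 <- threshold_mortality_scan(d0, cvhr, t, e,
                                    thresholds = seq(30, 300, by = 30))
  expect_true(all(diff(scan0$threshold_min) > 0))
  overall <- mean(d0$e) * 100
  expect_true(all(scan0$ci_low_pct <= overall & scan0$ci_high_pct >= overall))

  # planted: hazard doubled below 72 min
  lam <- ifelse(cvhr_min <= 72, 0.12, 0.04)
  d1 <- tibble::tibble(cvhr = cvhr_min, t = pmin(rexp(n, lam), 5))
  d1$e <- as.integer(d1$t < 5)
  scan1 <- threshold_mortality_scan(d1, cvhr, t, e,
                                    thresholds = c(40, 72, 150, 300))
  # mortality declines once thresholds admit low-hazard patients
  expect_gt(scan1$mortality_pct[2], scan1$mortality_pct[3])
  expect_gt(scan1$mortality_pct[3], scan1$mortality_pct[4])
  expect_gt(scan1$mortality_pct[1], scan1$mortality_pct[4])

  # constant cvhr value: single subgroup, curve constant beyond it
  d2 <- tibble::tibble(cvhr = rep(50, 100), t = pmin(rexp(100, 0.1), 5))
  d2$e <- as.integer(d2$t < 5)
  scan2 <- threshold_mortality_scan(d2, cvhr, t, e,
                                    thresholds = c(10, 50, 100, 200))
  expect_equal(nrow(scan2), 3)  # tau = 10 has an empty subgroup
  expect_equal(length(unique(scan2$mortality_pct)), 1)
})

test_that("small subgroups are suppressed in the scan", {
  d <- tibble::tibble(cvhr = c(rep(5, 5), rep(100, 50)),
                      t = rexp(55, 0.2), e = rbinom(55, 1, 0.8))
  scan <- threshold_mortality_scan(d, cvhr, t, e, thresholds = c(5, 100),
                                   min_n = 20)
  expect_equal(scan$threshold_min, 100)
})

test_that("Pearson correlation handles exact and null cases", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_warning(r <- pearson_r(rep(1, 10), 1:10), "zero variance")
  expect_true(is.na(r))

  # independent pairs at the cohort's non-flat sample size stay below 0.07
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    if (abs(pearson_r(rnorm(1513), rnorm(1513))) < 0.07) hits <- hits + 1
  }
  expect_gte(hits, 45)
})
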