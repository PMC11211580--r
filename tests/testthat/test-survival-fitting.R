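# Least-squares fitting of parametric families to digitized KM points,
# AIC selection, and survival/median evaluation.

test_that("survival_value matches closed forms and starts at 1", {
  f <- lnorm_fit(log(5.6), 0.8)
  expect_equal(survival_value(f, 5.6), 0.5)  # median of a lognormal
  # sigma calibrated by normal-quantile inversion so S(12) = 0.248
  sigma <- (log(12) - log(5.6)) / qnorm(1 - 0.248)
  expect_equal(survival_value(lnorm_fit(log(5.6), sigma), 12), 0.248,
               tolerance = 1e-12)
  for (fam in survival_families()) {
    set.seed(42)
    fit <- parametric_fit(fam, random_family_params(fam))
    expect_equal(survival_value(fit, 0), 1, info = fam)
  }
  expect_error(survival_value(f, -1), "non-negative")
  expect_error(parametric_fit("lognormal", c(1, NaN)), "non-finite")
})

test_that("survival functions are monotone and bounded for random parameters", {
  t_grid <- c(0, 10^seq(-2, 2, length.out = 60))
  for (fam in survival_families()) {
    for (rep in 1:10) {
      set.seed(100 * rep + match(fam, survival_families()))
      fit <- parametric_fit(fam, random_family_params(fam))
      s <- survival_value(fit, t_grid)
      expect_true(all(s >= 0 & s <= 1), info = fam)
      expect_true(all(diff(s) <= 1e-12), info = fam)
      expect_equal(s[1], 1, info = fam)
    }
  }
})

test_that("least-squares fitting recovers noiseless generating parameters", {
  truth <- list(
    exponential = c(rate = 0.1),
    weibull = c(shape = 1.3, scale = 8),
    gamma = c(shape = 1.6, rate = 0.25),
    gengamma = c(mu = 1.8, sigma = 0.9, Q = 0.5),
    gompertz = c(shape = 0.08, rate = 0.07),
    lognormal = c(meanlog = log(5.6), sdlog = 0.9),
    loglogistic = c(shape = 1.8, scale = 6)
  )
  for (fam in names(truth)) {
    rec <- curve_recipe(fam, truth[[fam]], n_points = 40, t_max = 18,
                        noise_sd = 0, seed = 1)
    fit <- fit_curve(generate_km_points(rec), fam)
    expect_true(fit$converged, info = fam)
    rel <- abs(fit$params - truth[[fam]]) / pmax(abs(truth[[fam]]), 1e-8)
    expect_lt(max(rel), 1e-3, label = paste(fam, "relative error"))
  }
})

test_that("under-determined curves are rejected", {
  cur <- digitized_curve(c(1, 2, 3, 4), c(0.9, 0.8, 0.7, 0.6))
  expect_error(fit_curve(cur, "gengamma"), "at least 5 points")
  cur2 <- digitized_curve(c(1, 2), c(0.9, 0.8))
  expect_error(fit_curve(cur2, "exponential"), "at least")
})

test_that("digitized_curve enforces monotone bounded coordinates", {
  expect_error(digitized_curve(c(1, 1, 2), c(0.9, 0.8, 0.7)),
               "strictly increasing")
  expect_error(digitized_curve(c(1, 2), c(0.5, 0.8)), "increase")
  expect_error(digitized_curve(c(1, 2), c(1.2, 0.8)), "\\[0, 1\\]")
  # plateaus and sub-1e-9 wobbles are fine
  cur <- digitized_curve(c(1, 2, 3), c(0.8, 0.8, 0.8 + 1e-12))
  expect_true(all(diff(cur$survival) <= 0))
})

test_that("AIC selection picks the minimal-AIC family deterministically", {
  # same n, larger rss => larger AIC
  f_exp <- parametric_fit("exponential", c(rate = 0.1), rss = 0.5, n = 20)
  f_ln <- lnorm_fit(log(5), 1)
  f_ln$rss <- 0.1; f_ln$n <- 20L
  f_ln$aic <- 20 * log(0.1 / 20) + 2 * 2
  sel <- select_by_aic(list(f_exp, f_ln))
  expect_identical(sel$best, "lognormal")
  expect_true(sel$table$selected[sel$table$family == "lognormal"])

  # exact tie: fewer parameters win, then fixed family order
  f_a <- parametric_fit("weibull", c(shape = 1, scale = 5), rss = 1, n = 20)
  f_b <- parametric_fit("lognormal", c(meanlog = 1, sdlog = 1), rss = 1, n = 20)
  expect_identical(select_by_aic(list(f_b, f_a))$best, "weibull")
  f_c <- parametric_fit("exponential", c(rate = 0.1), rss = 1, n = 20)
  f_c$aic <- f_a$aic  # force an exact tie across k
  expect_identical(select_by_aic(list(f_a, f_c))$best, "exponential")

  # single successful fit
  f_bad <- parametric_fit("gamma", c(shape = 1, rate = 0.1), rss = 0.01,
                          n = 20, converged = FALSE)
  expect_identical(select_by_aic(list(f_bad, f_exp))$best, "exponential")
  expect_error(select_by_aic(list(f_bad)), "all families failed")
})

test_that("low-noise lognormal data yields a lognormal AIC selection", {
  f0 <- lognormal_from_summaries(5.6, 0.248, 12)
  rec <- curve_recipe("lognormal", f0$params, n_points = 40, t_max = 18,
                      noise_sd = 0.005, seed = 1)
  sel <- fit_all_families(generate_km_points(rec))
  expect_identical(sel$best, "lognormal")
  expect_equal(nrow(sel$table), 7)
  expect_equal(sum(sel$table$selected), 1)
})

test_that("median_survival matches closed forms and a grid-inversion oracle", {
  expect_equal(median_survival(lnorm_fit(log(5.6), 0.37)), 5.6)
  expect_equal(median_survival(exp_fit(0.2)), log(2) / 0.2)
  # gompertz: brute-force dense-grid inversion at step 1e-4
  g <- parametric_fit("gompertz", c(shape = 0.09, rate = 0.06))
  grid <- seq(0, 60, by = 1e-4)
  oracle <- grid[which.max(survival_value(g, grid) <= 0.5)]
  expect_equal(median_survival(g), oracle, tolerance = 1e-3)
  # |S(median) - 0.5| < 1e-6 whenever the median exists
  for (fam in survival_families()) {
    set.seed(7 + match(fam, survival_families()))
    fit <- parametric_fit(fam, random_family_params(fam))
    m <- median_survival(fit)
    if (!is.na(m)) expect_lt(abs(survival_value(fit, m) - 0.5), 1e-6)
  }
  # plateau above 0.5: undefined-median marker
  plateau <- parametric_fit("gompertz", c(shape = -0.5, rate = 0.1))
  expect_true(is.na(median_survival(plateau)))
})

test_that("endpoint coherence reports exactly the analytic crossing region", {
  os <- lnorm_fit(log(5), 0.5)
  pfs <- lnorm_fit(log(5), 1)
  grid <- seq(0.5, 20, by = 0.5)
  # same median, flatter PFS: curves cross at t = 5, PFS above beyond it
  rep <- enforce_endpoint_coherence(os, pfs, grid)
  expect_identical(rep$violations, grid[grid > 5])
  direct <- grid[survival_value(os, grid) < survival_value(pfs, grid)]
  expect_identical(rep$violations, direct)
  # identical fits and uniformly higher OS: no violations
  expect_length(enforce_endpoint_coherence(os, os, grid)$violations, 0)
  os_hi <- lnorm_fit(log(9), 1)
  expect_length(enforce_endpoint_coherence(os_hi, pfs, grid)$violations, 0)
})

test_that("curve files and fit reports round-trip through their readers", {
  rec <- curve_recipe("lognormal", c(meanlog = log(5), sdlog = 1),
                      n_points = 12, t_max = 18, noise_sd = 0.01, seed = 3)
  cur <- generate_km_points(rec, arm = "sotorasib", endpoint = "PFS")
  path <- withr::local_tempfile(fileext = ".csv")
  write_digitized_curve(cur, path)
  back <- read_digitized_curve(path, arm = "sotorasib", endpoint = "PFS")
  expect_equal(back$time_months, cur$time_months)
  expect_equal(back$survival, cur$survival)
  rep <- fit_report(fit_all_families(cur))
  expect_named(rep, c("family", "params", "k", "rss", "aic", "converged",
                      "selected"))
  expect_equal(sum(rep$selected), 1)
})
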