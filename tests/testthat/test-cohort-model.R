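# Partitioned-survival trace construction and discounted cost/QALY
# accumulation.

test_that("state membership partitions the cohort and clips incoherent tails", {
  f <- exp_fit(0.1)
  occ0 <- state_membership(f, f, 0)
  expect_equal(unlist(occ0), c(pfs = 1, pd = 0, dead = 0))
  # S_OS = 0.6, S_PFS = 0.25 at a known time via two exponentials
  t <- 5
  os <- exp_fit(-log(0.6) / t)
  pfs <- exp_fit(-log(0.25) / t)
  occ <- state_membership(pfs, os, t)
  expect_equal(unlist(occ), c(pfs = 0.25, pd = 0.35, dead = 0.40),
               tolerance = 1e-12)
  # incoherent tail S_PFS > S_OS: PD clipped at 0, occupancy conserved
  os2 <- exp_fit(-log(0.2) / t)
  pfs2 <- exp_fit(-log(0.3) / t)
  occ2 <- state_membership(pfs2, os2, t)
  expect_equal(unlist(occ2), c(pfs = 0.3, pd = 0, dead = 0.7),
               tolerance = 1e-12)
  expect_equal(occ2$pfs + occ2$pd + occ2$dead, 1)
})

test_that("trace matches exponential closed forms", {
  config <- model_config(n_cycles = 120, half_cycle_correction = FALSE)
  # equal PFS and OS rates: nobody occupies PD
  tr_eq <- build_trace(config, exp_fit(0.1), exp_fit(0.1))
  expect_true(all(tr_eq$pd == 0))
  # dead fraction at cycle 120 (monthly cycles) is 1 - exp(-12)
  tr <- build_trace(config, exp_fit(0.2), exp_fit(0.1))
  expect_equal(tr$dead[120], 1 - exp(-12), tolerance = 1e-9)
  expect_equal(nrow(tr), 120)
  # single-cycle trace
  tr1 <- build_trace(model_config(n_cycles = 1), exp_fit(0.2), exp_fit(0.1))
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$time_months, 0.5)  # half-cycle correction default ON
})

test_that("trace occupancies always sum to one and deaths accumulate", {
  for (rep in 1:8) {
    set.seed(rep)
    fam_p <- sample(survival_families(), 1)
    fam_o <- sample(survival_families(), 1)
    pfs <- parametric_fit(fam_p, random_family_params(fam_p))
    os <- parametric_fit(fam_o, random_family_params(fam_o))
    tr <- build_trace(model_config(n_cycles = 60), pfs, os)
    expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(tr$new_deaths >= 0))
    expect_true(all(diff(tr$pfs) <= 1e-12))
  }
})

test_that("discount factor follows 1/(1+r)^t", {
  expect_equal(discount_factor(0, c(0, 1, 7)), c(1, 1, 1))
  expect_equal(discount_factor(0.05, 1), 1 / 1.05)
  # repeated-multiplication oracle for 2.5 years at 3%
  expect_equal(discount_factor(0.03, 2.5), 1 / (1.03 * 1.03 * sqrt(1.03)),
               tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1), "non-negative")
  expect_error(discount_factor(0.03, -1), "non-negative")
})

test_that("docetaxel dosing supports BSA, vial rounding and flat override", {
  expect_equal(docetaxel_dose(1.72, fixed_dose_mg = 140), 140)
  expect_equal(docetaxel_dose(1.82, 75), 136.5)
  expect_equal(docetaxel_dose(1.82, 75, vial_size_mg = 20), 140)
  expect_error(docetaxel_dose(-1, 75), "positive")
})

test_that("arm totals match a geometric-series oracle for exponential arms", {
  zero_cost <- cost_set()
  zero_util <- utility_set(0, 0)
  cfg0 <- model_config(n_cycles = 60, discount_rate_cost = 0,
                       discount_rate_qaly = 0, half_cycle_correction = FALSE)
  r0 <- run_arm(cfg0, zero_cost, zero_util, exp_fit(0.1), exp_fit(0.1))
  expect_equal(r0$total_cost, 0)
  expect_equal(r0$total_qaly, 0)

  lambda <- 0.08; c_drug <- 500; u <- 0.75
  costs <- cost_set(drug_cost_per_cycle = c_drug)
  utils_ <- utility_set(u, 0)
  r <- run_arm(cfg0, costs, utils_, exp_fit(lambda), exp_fit(lambda))
  t_c <- 1:60  # monthly cycle boundaries
  expect_equal(r$total_cost, c_drug * sum(exp(-lambda * t_c)),
               tolerance = 1e-9)
  expect_equal(r$total_qaly, u * (1 / 12) * sum(exp(-lambda * t_c)),
               tolerance = 1e-9)
  # discounting strictly reduces QALYs
  cfg_d <- model_config(n_cycles = 60, discount_rate_qaly = 0.05,
                        half_cycle_correction = FALSE)
  r_d <- run_arm(cfg_d, costs, utils_, exp_fit(lambda), exp_fit(lambda))
  expect_lt(r_d$total_qaly, r$total_qaly)
  # breakdown components sum to totals
  expect_equal(sum(r_d$cost_breakdown), r_d$total_cost, tolerance = 1e-6)
  expect_equal(sum(r_d$qaly_breakdown), r_d$total_qaly, tolerance = 1e-6)
})

test_that("costs scale linearly and utilities scale QALYs linearly", {
  setup <- tiny_model_setup()
  arm <- setup$intervention
  r1 <- run_arm(setup$config, arm$costs, arm$utilities, arm$pfs_fit,
                arm$os_fit)
  costs2 <- arm$costs
  for (f in c("drug_cost_per_cycle", "followup_cost_per_cycle",
              "hospitalization_cost_per_cycle", "bsc_cost_per_cycle",
              "terminal_cost")) costs2[[f]] <- 2 * costs2[[f]]
  costs2$ae_events$unit_cost <- 2 * costs2$ae_events$unit_cost
  r2 <- run_arm(setup$config, costs2, arm$utilities, arm$pfs_fit, arm$os_fit)
  expect_equal(r2$total_cost, 2 * r1$total_cost, tolerance = 1e-9)
  util_half <- utility_set(0.4, 0.15)
  r3 <- run_arm(setup$config, arm$costs, utility_set(0.8, 0.3),
                arm$pfs_fit, arm$os_fit)
  r4 <- run_arm(setup$config, arm$costs, util_half, arm$pfs_fit, arm$os_fit)
  expect_equal(r4$total_qaly, 0.5 * r3$total_qaly, tolerance = 1e-9)
})

test_that("short cycles converge to the continuous-time closed form", {
  lambda <- 0.1; u <- 0.8; r_annual <- 0.05
  horizon_months <- 60
  pfs <- exp_fit(lambda); os <- exp_fit(lambda)
  utils_ <- utility_set(u, 0)
  # continuous-time QALY integral over the horizon (months -> years)
  r_m <- log(1 + r_annual) / 12
  integrand <- function(t) u * exp(-lambda * t) * exp(-r_m * t) / 12
  target <- stats::integrate(integrand, 0, horizon_months)$value
  # weekly cycles with half-cycle correction agree within 1%
  cfg_w <- model_config(cycle_length_days = 7,
                        n_cycles = round(horizon_months * 30.4375 / 7),
                        discount_rate_qaly = r_annual)
  r_week <- run_arm(cfg_w, cost_set(), utils_, pfs, os)
  expect_equal(r_week$total_qaly, target, tolerance = 0.01)
  # halving cycle length over the same horizon shifts totals by < 2%
  cfg_m <- model_config(n_cycles = 60, discount_rate_qaly = r_annual)
  cfg_h <- model_config(cycle_length_days = 30.4375 / 2, n_cycles = 120,
                        discount_rate_qaly = r_annual)
  q_m <- run_arm(cfg_m, cost_set(), utils_, pfs, os)$total_qaly
  q_h <- run_arm(cfg_h, cost_set(), utils_, pfs, os)$total_qaly
  expect_lt(abs(q_h - q_m) / q_m, 0.02)
})

test_that("trace output table round-trips with discounted accumulators", {
  setup <- tiny_model_setup()
  arm <- setup$intervention
  r <- run_arm(setup$config, arm$costs, arm$utilities, arm$pfs_fit,
               arm$os_fit)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(r, setup$config, arm$costs, arm$utilities, path)
  back <- read.delim(path)
  expect_equal(nrow(back), setup$config$n_cycles)
  expect_named(back, c("cycle", "time_months", "pfs", "pd", "dead",
                       "new_deaths", "disc_cost", "disc_qaly"))
  # per-cycle discounted sums reproduce the totals net of one-time AE items
  ae_cost <- sum(arm$costs$ae_events$incidence *
                   arm$costs$ae_events$unit_cost) *
    discount_factor(setup$config$discount_rate_cost, back$time_months[1] / 12)
  expect_equal(sum(back$disc_cost) + ae_cost, r$total_cost,
               tolerance = 1e-6)
  expect_equal(sum(back$disc_qaly), r$total_qaly, tolerance = 1e-6)
})
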