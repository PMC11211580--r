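# One-way (tornado) sensitivity analysis, distribution moment matching,
# probabilistic sensitivity analysis and acceptability curves.

test_that("default bounds are +/-20% with utility cap at 1", {
  expect_equal(default_bounds(100), c(80, 120))
  expect_equal(default_bounds(0), c(0, 0))
  expect_equal(default_bounds(0.9, is_utility = TRUE), c(0.72, 1))
})

test_that("moment matching reproduces textbook identities", {
  g <- moment_match(100, 100 - 1.96 * 10, 100 + 1.96 * 10, "gamma")
  expect_equal(unname(g$params), c(100, 1))
  b <- moment_match(0.5, 0.5 - 1.96 * 0.1, 0.5 + 1.96 * 0.1, "beta")
  expect_equal(unname(b$params), c(12, 12))
  # sampled moments agree with the target over 1e5 seeded draws
  set.seed(99)
  draws_b <- rbeta(1e5, b$params[["shape1"]], b$params[["shape2"]])
  expect_equal(mean(draws_b), 0.5, tolerance = 0.01)
  expect_equal(sd(draws_b), 0.1, tolerance = 0.03)
  draws_g <- rgamma(1e5, shape = g$params[["shape"]],
                    scale = g$params[["scale"]])
  expect_equal(mean(draws_g) / 100, 1, tolerance = 0.01)
  expect_equal(sd(draws_g) / 10, 1, tolerance = 0.03)
})

test_that("infeasible beta rows fall back to uniform with a warning", {
  # a cost-scale mean can never satisfy the beta identities
  expect_warning(mm <- moment_match(1209.58, 967.66, 1451.50, "beta"),
                 "falling back to uniform")
  expect_identical(mm$distribution, "uniform")
  expect_true(mm$fallback)
  # impossible variance inside (0,1) also falls back
  expect_warning(mm2 <- moment_match(0.5, 0, 1.96, "beta"), "uniform")
  expect_true(mm2$fallback)
  # zero-width bounds give a point mass
  mm3 <- moment_match(5, 5, 5, "gamma")
  expect_identical(mm3$distribution, "degenerate")
})

test_that("tornado entries are spread-sorted with inert parameters at zero", {
  setup <- tiny_model_setup()
  model <- make_ce_model(setup$config, setup$intervention, setup$comparator)
  torn <- one_way(tiny_specs(setup), model)
  # AE disutility is ignored while apply_ae_disutility is off
  inert <- torn[torn$role == "sotorasib:ae_disutility:Diarrhoea", ]
  expect_equal(inert$spread, 0)
  # intervention drug cost: ICER rises with the bound
  drug <- torn[torn$role == "sotorasib:drug_cost_per_cycle", ]
  expect_gt(drug$icer_at_high, drug$icer_at_low)
  # sorting contract against a brute-force re-sort
  expect_identical(torn$spread, sort(torn$spread, decreasing = TRUE,
                                     na.last = TRUE))
  expect_false(any(torn$flagged))
  expect_equal(nrow(torn), 4)
})

test_that("degenerate PSA reproduces the deterministic base case exactly", {
  setup <- tiny_model_setup()
  model <- make_ce_model(setup$config, setup$intervention, setup$comparator)
  specs <- tiny_specs(setup)
  specs$low <- specs$high <- specs$base
  psa <- run_psa(specs, model, n_draws = 5, seed = 42)
  base <- model()
  expect_true(all(psa$results$cost_intervention ==
                    base$intervention$total_cost))
  expect_true(all(psa$results$qaly_comparator ==
                    base$comparator$total_qaly))
  # n_draws = 1 degenerate run is bit-for-bit the base case
  one <- run_psa(specs, model, n_draws = 1, seed = 7)
  expect_identical(one$results$cost_intervention,
                   base$intervention$total_cost)
  expect_identical(one$results$qaly_intervention,
                   base$intervention$total_qaly)
})

test_that("PSA is seed-reproducible and unbiased for its spec means", {
  setup <- tiny_model_setup()
  model <- make_ce_model(setup$config, setup$intervention, setup$comparator)
  specs <- tiny_specs(setup)
  p1 <- run_psa(specs, model, n_draws = 200, seed = 11)
  p2 <- run_psa(specs, model, n_draws = 200, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$results, p2$results)
  p3 <- run_psa(specs, model, n_draws = 200, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
  # sampled drug cost within 3 Monte Carlo standard errors of its mean
  drug <- p1$draws[, "sotorasib:drug_cost_per_cycle"]
  mm <- moment_match(1000, 800, 1200, "gamma")
  expect_lt(abs(mean(drug) - mm$mean), 3 * mm$sd / sqrt(length(drug)))
})

test_that("parameter substreams are stable when other parameters change", {
  setup <- tiny_model_setup()
  model <- make_ce_model(setup$config, setup$intervention, setup$comparator)
  specs <- tiny_specs(setup)
  full <- run_psa(specs, model, n_draws = 50, seed = 5)
  subset <- run_psa(specs[-2, ], model, n_draws = 50, seed = 5)
  expect_identical(full$draws[, "shared:u_pfs"],
                   subset$draws[, "shared:u_pfs"])
})

test_that("CEAC matches a counting oracle and is monotone when all gain QALYs", {
  # synthetic PSA with known per-draw ICERs, all delta-QALY > 0
  set.seed(31)
  n <- 400
  dq <- runif(n, 0.05, 0.5)
  icers <- runif(n, 1e4, 2e5)
  res <- data.frame(cost_intervention = icers * dq, qaly_intervention = dq,
                    cost_comparator = 0, qaly_comparator = 0)
  psa <- structure(list(n_draws = n, seed = 31, draws = NULL,
                        results = res, specs = NULL, n_failed = 0L),
                   class = "psa_run")
  grid <- seq(0, 250000, by = 2500)
  curve <- ceac(psa, grid)
  oracle <- vapply(grid, function(l) mean(icers < l), numeric(1))
  expect_equal(curve$p_intervention, oracle)
  expect_true(all(diff(curve$p_intervention) >= 0))
  expect_equal(curve$p_intervention + curve$p_comparator, rep(1, nrow(curve)))
  # lambda = 0: fraction of draws strictly cheaper (none here)
  expect_equal(curve$p_intervention[1], 0)
  # very large lambda with all delta-QALY > 0: probability reaches 1
  expect_equal(ceac(psa, c(0, 1e9))$p_intervention[2], 1)
})

test_that("CEAC crossover returns the first grid point at 50%", {
  pts <- data.frame(lambda = c(0, 1e5, 1.05e5),
                    p_intervention = c(0.1, 0.49, 0.55))
  expect_equal(ceac_crossover(pts), 105000)
  flat <- data.frame(lambda = c(0, 1e5), p_intervention = c(0.4, 0.4))
  expect_true(is.na(ceac_crossover(flat)))
  # all draws share one ICER: crossover at the first grid point above it
  res <- data.frame(cost_intervention = 50000 * 0.2, qaly_intervention = 0.2,
                    cost_comparator = 0, qaly_comparator = 0)
  psa1 <- structure(list(n_draws = 1, seed = 1, draws = NULL,
                         results = res, specs = NULL, n_failed = 0L),
                    class = "psa_run")
  grid <- seq(0, 100000, by = 2500)
  expect_equal(ceac_crossover(ceac(psa1, grid)), 52500)
})
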