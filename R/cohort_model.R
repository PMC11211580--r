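# Three-state partitioned-survival cohort model. State occupancy is read
# directly off the fitted PFS and OS curves at each cycle's evaluation
# time (midpoint when half-cycle correction is on):
#   PFS  = S_PFS(t)
#   PD   = max(0, S_OS(t) - S_PFS(t))
#   dead = 1 - S_OS(t)
# Costs and QALYs accumulate per cycle with annual discounting.

DAYS_PER_MONTH <- 30.4375  # 365.25 / 12

#' Model run configuration
#'
#' @param cycle_length_days Cycle length in days. Default 30.4375 (one
#'   month), giving a 10-year horizon at the default 120 cycles.
#' @param n_cycles Number of model cycles (default 120).
#' @param discount_rate_cost,discount_rate_qaly Annual discount rates as
#'   fractions in \[0, 0.2\].
#' @param half_cycle_correction Evaluate occupancy at cycle midpoints
#'   (default TRUE) rather than cycle ends.
#' @param apply_ae_disutility Apply the one-time adverse-event QALY
#'   decrement (default FALSE; the base case ignores AE disutilities).
#' @param currency_per_usd Exchange rate used to convert local-currency
#'   inputs to USD at load time (default 6.92 RMB/USD).
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_length_days = DAYS_PER_MONTH,
                         n_cycles = 120L,
                         discount_rate_cost = 0.05,
                         discount_rate_qaly = 0.05,
                         half_cycle_correction = TRUE,
                         apply_ae_disutility = FALSE,
                         currency_per_usd = 6.92) {
  stopifnot(cycle_length_days > 0, n_cycles >= 1,
            discount_rate_cost >= 0, discount_rate_cost <= 0.2,
            discount_rate_qaly >= 0, discount_rate_qaly <= 0.2,
            currency_per_usd > 0)
  structure(list(cycle_length_days = cycle_length_days,
                 n_cycles = as.integer(n_cycles),
                 discount_rate_cost = discount_rate_cost,
                 discount_rate_qaly = discount_rate_qaly,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 apply_ae_disutility = isTRUE(apply_ae_disutility),
                 currency_per_usd = currency_per_usd),
            class = "model_config")
}

#' Per-arm cost inputs
#'
#' All values in USD. Per-cycle costs accrue against state occupancy:
#' drug while progression-free (treat-to-progression), follow-up and
#' hospitalization while alive, best supportive care while progressed.
#' Terminal care is a one-time cost per new death; grade >= 3
#' adverse-event costs are one-time, incidence-weighted, in cycle 1.
#'
#' @param drug_cost_per_cycle,followup_cost_per_cycle,hospitalization_cost_per_cycle,bsc_cost_per_cycle
#'   Non-negative per-cycle costs.
#' @param terminal_cost One-time cost at death entry.
#' @param ae_events Data frame with columns `label`, `incidence` (in
#'   \[0,1\]) and `unit_cost`.
#' @return An object of class `cost_set`.
#' @export
cost_set <- function(drug_cost_per_cycle = 0,
                     followup_cost_per_cycle = 0,
                     hospitalization_cost_per_cycle = 0,
                     bsc_cost_per_cycle = 0,
                     terminal_cost = 0,
                     ae_events = NULL) {
  if (is.null(ae_events)) {
    ae_events <- data.frame(label = character(), incidence = numeric(),
                            unit_cost = numeric())
  }
  money <- c(drug_cost_per_cycle, followup_cost_per_cycle,
             hospitalization_cost_per_cycle, bsc_cost_per_cycle,
             terminal_cost, ae_events$unit_cost)
  stopifnot(all(is.finite(money)), all(money >= 0),
            all(ae_events$incidence >= 0), all(ae_events$incidence <= 1))
  structure(list(drug_cost_per_cycle = drug_cost_per_cycle,
                 followup_cost_per_cycle = followup_cost_per_cycle,
                 hospitalization_cost_per_cycle = hospitalization_cost_per_cycle,
                 bsc_cost_per_cycle = bsc_cost_per_cycle,
                 terminal_cost = terminal_cost,
                 ae_events = ae_events),
            class = "cost_set")
}

#' Per-arm health-state utilities
#'
#' @param u_pfs,u_pd Utilities of the progression-free and progressed
#'   states, in \[0, 1\]. A user-supplied `u_pd > u_pfs` triggers a
#'   warning, not an error.
#' @param ae_disutilities Data frame with columns `label`, `incidence`
#'   and `disutility` (per-event utility decrement); only used when the
#'   model config enables `apply_ae_disutility`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_pfs, u_pd, ae_disutilities = NULL) {
  stopifnot(u_pfs >= 0, u_pfs <= 1, u_pd >= 0, u_pd <= 1)
  if (u_pd > u_pfs) {
    warning("u_pd > u_pfs: progressed state valued above progression-free")
  }
  if (is.null(ae_disutilities)) {
    ae_disutilities <- data.frame(label = character(), incidence = numeric(),
                                  disutility = numeric())
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd,
                 ae_disutilities = ae_disutilities),
            class = "utility_set")
}

#' Discount factor
#'
#' @param annual_rate Annual discount rate (fraction, >= 0).
#' @param elapsed_years Elapsed time in years (>= 0); vectorised.
#' @return 1 / (1 + rate)^elapsed_years.
#' @export
discount_factor <- function(annual_rate, elapsed_years) {
  if (any(annual_rate < 0) || any(elapsed_years < 0)) {
    stop("discount rate and elapsed time must be non-negative")
  }
  exp(-elapsed_years * log1p(annual_rate))
}

#' Partitioned-survival state membership at a time point
#'
#' Occupancy read off the two curves; when extrapolated tails are
#' incoherent (S_PFS > S_OS) PD is clipped at 0 and dead set to 1 - PFS so
#' the three occupancies still sum to 1.
#'
#' @param pfs_fit,os_fit [parametric_fit()] objects.
#' @param t Time(s) in months; vectorised.
#' @return Data frame with columns `pfs`, `pd`, `dead` summing to 1.
#' @export
state_membership <- function(pfs_fit, os_fit, t) {
  s_pfs <- survival_value(pfs_fit, t)
  s_os <- survival_value(os_fit, t)
  pd <- pmax(0, s_os - s_pfs)
  dead <- ifelse(s_os < s_pfs, 1 - s_pfs, 1 - s_os)
  data.frame(pfs = s_pfs, pd = pd, dead = dead)
}

#' Build the cohort trace
#'
#' Occupancy evaluated at cycle boundaries, or midpoints when the
#' half-cycle correction is on. New deaths per cycle are first
#' differences of the dead fraction, floored at 0.
#'
#' @param config A [model_config()].
#' @param pfs_fit,os_fit [parametric_fit()] objects.
#' @return An object of class `cohort_trace`: data frame with columns
#'   `cycle`, `time_months`, `pfs`, `pd`, `dead`, `new_deaths`.
#' @export
build_trace <- function(config, pfs_fit, os_fit) {
  stopifnot(inherits(config, "model_config"))
  cm <- config$cycle_length_days / DAYS_PER_MONTH
  cycles <- seq_len(config$n_cycles)
  t_eval <- if (config$half_cycle_correction) (cycles - 0.5) * cm else cycles * cm
  occ <- state_membership(pfs_fit, os_fit, t_eval)
  new_deaths <- pmax(0, diff(c(0, occ$dead)))
  out <- data.frame(cycle = cycles, time_months = t_eval,
                    pfs = occ$pfs, pd = occ$pd, dead = occ$dead,
                    new_deaths = new_deaths)
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Docetaxel dose from body surface area
#'
#' dose = dose_per_m2 x BSA, optionally rounded up to whole vials; a
#' fixed-dose override represents the flat 140 mg single dose.
#'
#' @param bsa_m2 Body surface area in m^2 (> 0); e.g. 1.72 (China),
#'   1.82 (US).
#' @param dose_per_m2 Dose intensity in mg/m^2 (default 75).
#' @param fixed_dose_mg If not NULL, returned as-is (flat-dose override).
#' @param vial_size_mg If not NULL, the BSA-based dose is rounded up to a
#'   multiple of this vial size.
#' @return Dose in mg.
#' @export
docetaxel_dose <- function(bsa_m2, dose_per_m2 = 75, fixed_dose_mg = NULL,
                           vial_size_mg = NULL) {
  if (!is.null(fixed_dose_mg)) {
    if (fixed_dose_mg <= 0) stop("fixed dose must be positive")
    return(fixed_dose_mg)
  }
  if (bsa_m2 <= 0 || dose_per_m2 <= 0) {
    stop("body surface area and dose intensity must be positive")
  }
  dose <- dose_per_m2 * bsa_m2
  if (!is.null(vial_size_mg)) dose <- ceiling(dose / vial_size_mg) * vial_size_mg
  dose
}

#' Run one treatment arm through the cohort model
#'
#' Accumulates discounted costs (drug in PFS, follow-up and
#' hospitalization while alive, best supportive care in PD, terminal care
#' per new death, one-time incidence-weighted AE costs in cycle 1) and
#' discounted QALYs (state occupancy x utility x cycle length, minus the
#' optional one-cycle AE disutility burden).
#'
#' @param config A [model_config()].
#' @param costs A [cost_set()].
#' @param utilities A [utility_set()].
#' @param pfs_fit,os_fit [parametric_fit()] objects.
#' @param trace Optional precomputed [build_trace()] result (the trace
#'   depends only on the fits and cycle structure, so sensitivity
#'   analyses can reuse it across cost/utility draws).
#' @return An object of class `arm_result`: list with `total_cost`,
#'   `total_qaly`, `cost_breakdown`, `qaly_breakdown`, `trace`.
#' @export
run_arm <- function(config, costs, utilities, pfs_fit = NULL, os_fit = NULL,
                    trace = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(costs, "cost_set"),
            inherits(utilities, "utility_set"))
  if (is.null(trace)) trace <- build_trace(config, pfs_fit, os_fit)
  cm <- config$cycle_length_days / DAYS_PER_MONTH
  cycle_years <- cm / 12
  years <- trace$time_months / 12
  disc_c <- discount_factor(config$discount_rate_cost, years)
  disc_q <- discount_factor(config$discount_rate_qaly, years)
  alive <- trace$pfs + trace$pd

  cost_drug <- sum(disc_c * costs$drug_cost_per_cycle * trace$pfs)
  cost_followup <- sum(disc_c * costs$followup_cost_per_cycle * alive)
  cost_hosp <- sum(disc_c * costs$hospitalization_cost_per_cycle * alive)
  cost_bsc <- sum(disc_c * costs$bsc_cost_per_cycle * trace$pd)
  cost_terminal <- sum(disc_c * costs$terminal_cost * trace$new_deaths)
  cost_ae <- sum(costs$ae_events$incidence * costs$ae_events$unit_cost) *
    disc_c[1]

  qaly_pfs <- sum(disc_q * cycle_years * utilities$u_pfs * trace$pfs)
  qaly_pd <- sum(disc_q * cycle_years * utilities$u_pd * trace$pd)
  qaly_ae <- if (config$apply_ae_disutility) {
    -sum(utilities$ae_disutilities$incidence *
           utilities$ae_disutilities$disutility) * cycle_years * disc_q[1]
  } else 0

  cost_breakdown <- c(drug = cost_drug, followup = cost_followup,
                      hospitalization = cost_hosp, bsc = cost_bsc,
                      terminal = cost_terminal, ae = cost_ae)
  qaly_breakdown <- c(pfs = qaly_pfs, pd = qaly_pd, ae = qaly_ae)
  structure(list(total_cost = sum(cost_breakdown),
                 total_qaly = sum(qaly_breakdown),
                 cost_breakdown = cost_breakdown,
                 qaly_breakdown = qaly_breakdown,
                 trace = trace),
            class = "arm_result")
}

#' Write a cohort trace with discounted per-cycle accumulators
#'
#' Emits the delimited trace table: cycle, time_months, pfs, pd, dead,
#' new_deaths, disc_cost, disc_qaly.
#'
#' @param arm An [run_arm()] result.
#' @param config The [model_config()] used.
#' @param costs,utilities The inputs used.
#' @param path Output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_trace <- function(arm, config, costs, utilities, path) {
  trace <- arm$trace
  cm <- config$cycle_length_days / DAYS_PER_MONTH
  years <- trace$time_months / 12
  disc_c <- discount_factor(config$discount_rate_cost, years)
  disc_q <- discount_factor(config$discount_rate_qaly, years)
  alive <- trace$pfs + trace$pd
  per_cycle_cost <- disc_c * (costs$drug_cost_per_cycle * trace$pfs +
    (costs$followup_cost_per_cycle + costs$hospitalization_cost_per_cycle) *
      alive + costs$bsc_cost_per_cycle * trace$pd +
    costs$terminal_cost * trace$new_deaths)
  per_cycle_qaly <- disc_q * (cm / 12) *
    (utilities$u_pfs * trace$pfs + utilities$u_pd * trace$pd)
  out <- cbind(as.data.frame(trace), disc_cost = per_cycle_cost,
               disc_qaly = per_cycle_qaly)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm result: total cost $%.2f, total QALYs %.4f\n",
              x$total_cost, x$total_qaly))
  cat("  cost breakdown: ",
      paste(sprintf("%s %.2f", names(x$cost_breakdown), x$cost_breakdown),
            collapse = ", "), "\n")
  invisible(x)
}
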