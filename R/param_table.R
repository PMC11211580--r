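# Parameter table: costs, utilities and adverse-event inputs with
# base/low/high values and a sampling distribution family, in the shape of
# a published model-input table. Rows whose values are not available in
# the source material (US costs, follow-up and hospitalization unit costs,
# grade >= 3 AE incidences) are synthetic placeholders and carry
# `synthetic = TRUE`.
#
# Each row maps into the cohort model through a `role` string:
#   config:discount_rate
#   <arm>:drug_cost_per_cycle
#   shared:{followup|hospitalization|bsc}_cost_per_cycle, shared:terminal_cost
#   shared:u_pfs, shared:u_pd
#   <arm>:ae_cost:<event>, <arm>:ae_incidence:<event>, <arm>:ae_disutility:<event>

param_row <- function(name, arm, category, event, base, low, high,
                      distribution, synthetic, source, psa = TRUE) {
  data.frame(name = name, arm = arm, category = category, event = event,
             base = base, low = low, high = high,
             distribution = distribution, synthetic = synthetic,
             source = source, psa = psa, stringsAsFactors = FALSE)
}

#' Default one-way sensitivity bounds
#'
#' Parameters lacking published limits are swept at +/-20% of the base
#' value; utility upper bounds are additionally capped at 1.
#'
#' @param base Base value (finite).
#' @param is_utility Cap the upper bound at 1 (default FALSE).
#' @return Numeric vector `c(low, high)`.
#' @export
default_bounds <- function(base, is_utility = FALSE) {
  stopifnot(is.finite(base))
  lo <- 0.8 * base
  hi <- 1.2 * base
  if (is_utility) hi <- min(hi, 1)
  c(lo, hi)
}

ae_cost_rows <- function(arm, suffix, events) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    param_row(paste0("C_", gsub(" ", "", e$event), "_", suffix), arm,
              "ae_cost", e$event, e$base, e$low, e$high, "beta", FALSE,
              "Medicare")
  }))
}

ae_util_rows <- function(arm, suffix, events, source) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    param_row(paste0("U_", gsub(" ", "", e$event), "_", suffix), arm,
              "ae_utility", e$event, e$base, e$low, e$high, "beta", FALSE,
              source)
  }))
}

ae_inc_rows <- function(arm, suffix, events) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    b <- default_bounds(e$inc, is_utility = TRUE)
    param_row(paste0("P_", gsub(" ", "", e$event), "_", suffix), arm,
              "ae_incidence", e$event, e$inc, b[1], b[2], "beta", TRUE,
              "synthetic grade >=3 incidence placeholder")
  }))
}

#' Model parameter table for one perspective
#'
#' Returns the full cost/utility/adverse-event input table for the China
#' or US societal perspective. Published values are reproduced verbatim
#' (including one utility row whose printed base value lies outside its
#' own printed bounds, which triggers a validation warning); unavailable
#' values are synthetic placeholders flagged in the `synthetic` column.
#'
#' @param perspective `"china"` or `"us"`.
#' @return A data frame with columns name, arm, category, event, base,
#'   low, high, distribution, synthetic, source, psa.
#' @export
param_table <- function(perspective = c("china", "us")) {
  perspective <- match.arg(perspective)

  soto_ae_costs <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia",
              "Decreased appetite"),
    base = c(1209.58, 1185.92, 1209.58, 5394.51, 1209.58),
    low = c(967.66, 948.74, 967.66, 4315.61, 967.66),
    high = c(1451.50, 1423.10, 1451.50, 6473.41, 1451.50))
  doce_ae_costs <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia", "Stomatitis",
              "Asthenia", "Neutropenia", "Neuropathy peripheral", "Myalgia",
              "Arthralgia", "Febrile neutropenia", "Pneumonia"),
    base = c(1209.58, 1185.92, 1209.58, 5394.51, 1638.38, 1185.92, 2449.99,
             1453.53, 1932.79, 1932.79, 2449.99, 1789.55),
    low = c(967.66, 948.74, 967.66, 4315.61, 1310.70, 948.74, 1959.99,
            1162.82, 1546.23, 1546.23, 1959.99, 1431.64),
    high = c(1451.50, 1423.10, 1451.50, 6473.41, 1966.06, 1423.10, 2939.99,
             1744.24, 2319.35, 2319.35, 2939.99, 2147.46))
  soto_ae_utils <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia",
              "Decreased appetite"),
    base = c(0.22, 0.29, 0.02, 0.07, 0.39),
    low = c(0.18, 0.23, 0.16, 0.06, 0.12),
    high = c(0.26, 0.35, 0.24, 0.09, 0.47))
  doce_ae_utils <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia", "Neutropenia",
              "Mucositis", "Febrile neutropenia", "Pneumonia"),
    base = c(0.22, 0.29, 0.20, 0.07, 0.35, 0.53, 0.47, 0.50),
    low = c(0.18, 0.23, 0.16, 0.06, 0.28, 0.47, 0.38, 0.40),
    high = c(0.26, 0.35, 0.24, 0.09, 0.42, 0.57, 0.56, 0.60))
  # synthetic grade >=3 incidence placeholders for the named trial events
  soto_inc <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia",
              "Decreased appetite"),
    inc = c(0.12, 0.02, 0.01, 0.03, 0.01))
  doce_inc <- data.frame(
    event = c("Diarrhoea", "Fatigue", "Nausea", "Anaemia", "Stomatitis",
              "Asthenia", "Neutropenia", "Neuropathy peripheral", "Myalgia",
              "Arthralgia", "Febrile neutropenia", "Pneumonia"),
    inc = c(0.02, 0.06, 0.01, 0.05, 0.01, 0.02, 0.23, 0.01, 0.01, 0.01,
            0.05, 0.02))

  if (perspective == "china") {
    core <- rbind(
      param_row("C_Sotorasib", "sotorasib", "drug", NA, 16892.82, 13514.256,
                20271.384, "gamma", FALSE, "Micromedex RedBook"),
      param_row("C_docetaxel", "docetaxel", "drug", NA, 228.41, 11.83,
                2556.05, "gamma", FALSE, "Micromedex RedBook"),
      param_row("U_PFS", "shared", "state_utility", "PFS", 0.804, 0.536,
                0.84, "beta", FALSE, "Nafees 2017"),
      param_row("U_PD", "shared", "state_utility", "PD", 0.321, 0.031,
                0.321, "beta", FALSE, "Nafees 2017"),
      param_row("C_bestsupportive", "shared", "other_cost", NA, 4221, 3377,
                5065, "beta", FALSE, "Cheng 2021"),
      param_row("C_terminal", "shared", "other_cost", NA, 17185, 13748,
                20622, "beta", FALSE, "Cheng 2021"),
      param_row("C_followup", "shared", "other_cost", NA, 120, 96, 144,
                "gamma", TRUE, "synthetic per-cycle follow-up placeholder"),
      param_row("C_hospitalization", "shared", "other_cost", NA, 500, 400,
                600, "gamma", TRUE,
                "synthetic per-cycle hospitalization placeholder")
    )
    utils_s <- ae_util_rows("sotorasib", "S", soto_ae_utils, "Nafees 2017")
    utils_d <- ae_util_rows("docetaxel", "D", doce_ae_utils, "Nafees 2017")
  } else {
    core <- rbind(
      param_row("C_Sotorasib", "sotorasib", "drug", NA, 21000, 16800, 25200,
                "gamma", TRUE, "synthetic US list-price placeholder"),
      param_row("C_docetaxel", "docetaxel", "drug", NA, 600, 480, 720,
                "gamma", TRUE, "synthetic US placeholder"),
      param_row("U_PFS", "shared", "state_utility", "PFS", 0.754, 0.536,
                0.84, "beta", FALSE, "Nafees 2017"),
      param_row("U_PD", "shared", "state_utility", "PD", 0.095, 0.031,
                0.321, "beta", FALSE, "Nafees 2017"),
      param_row("C_bestsupportive", "shared", "other_cost", NA, 6000, 4800,
                7200, "gamma", TRUE, "synthetic US placeholder"),
      param_row("C_terminal", "shared", "other_cost", NA, 20000, 16000,
                24000, "gamma", TRUE, "synthetic US placeholder"),
      param_row("C_followup", "shared", "other_cost", NA, 800, 640, 960,
                "gamma", TRUE, "synthetic per-cycle follow-up placeholder"),
      param_row("C_hospitalization", "shared", "other_cost", NA, 2500, 2000,
                3000, "gamma", TRUE,
                "synthetic per-cycle hospitalization placeholder")
    )
    utils_s <- ae_util_rows("sotorasib", "S", soto_ae_utils, "Nafees 2017")
    utils_d <- ae_util_rows("docetaxel", "D", doce_ae_utils, "Nafees 2017")
  }
  out <- rbind(
    core, utils_s, utils_d,
    ae_cost_rows("sotorasib", "S", soto_ae_costs),
    ae_cost_rows("docetaxel", "D", doce_ae_costs),
    ae_inc_rows("sotorasib", "S", soto_inc),
    ae_inc_rows("docetaxel", "D", doce_inc)
  )
  rownames(out) <- NULL
  validate_param_table(out)
  out
}

#' Validate a parameter table
#'
#' Checks column presence, distribution labels, bound ordering and value
#' ranges. A base value outside its own printed bounds warns rather than
#' errors, so published tables can be reproduced verbatim.
#'
#' @param params A parameter table data frame.
#' @return The table, invisibly.
#' @export
validate_param_table <- function(params) {
  need <- c("name", "arm", "category", "base", "low", "high", "distribution")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("parameter table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad_dist <- setdiff(unique(tolower(params$distribution)),
                      c("beta", "gamma", "gamma1", "uniform"))
  if (length(bad_dist)) stop("unknown distributions: ",
                             paste(bad_dist, collapse = ", "))
  if (any(params$low > params$high)) {
    stop("rows with low > high: ",
         paste(params$name[params$low > params$high], collapse = ", "))
  }
  off <- params$base < params$low | params$base > params$high
  if (any(off)) {
    warning("base value outside [low, high] for: ",
            paste(params$name[off], collapse = ", "),
            " (reproduced as printed)")
  }
  invisible(params)
}

#' Read/write a parameter table as delimited text
#'
#' @param path File path (tab-delimited).
#' @param params A parameter table data frame (for writing).
#' @return The table (read) or `path` invisibly (write).
#' @export
read_param_table <- function(path) {
  params <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  validate_param_table(params)
  params
}

#' @rdname read_param_table
#' @export
write_param_table <- function(params, path) {
  utils::write.table(params, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Role string for one table row (see header comment).
param_role <- function(row) {
  ev <- if (is.na(row$event)) "" else gsub(" ", "", row$event)
  switch(row$category,
    drug = paste0(row$arm, ":drug_cost_per_cycle"),
    state_utility = paste0("shared:u_", tolower(row$event)),
    ae_cost = paste0(row$arm, ":ae_cost:", ev),
    ae_utility = paste0(row$arm, ":ae_disutility:", ev),
    ae_incidence = paste0(row$arm, ":ae_incidence:", ev),
    other_cost = {
      field <- c(C_bestsupportive = "bsc_cost_per_cycle",
                 C_terminal = "terminal_cost",
                 C_followup = "followup_cost_per_cycle",
                 C_hospitalization = "hospitalization_cost_per_cycle")[row$name]
      if (is.na(field)) stop("unmapped other_cost row: ", row$name)
      paste0("shared:", field)
    },
    stop("unmapped category: ", row$category)
  )
}

#' Sensitivity-analysis specs from a parameter table
#'
#' One spec per table row (name, role, base, low, high, distribution),
#' plus a discount-rate spec swept in the one-way analysis but held fixed
#' in the PSA (the probabilistic analysis samples cost and utility
#' distributions only).
#'
#' @param params A parameter table.
#' @param config A [model_config()] (supplies the discount-rate base).
#' @param discount_range Low/high bounds for the discount-rate sweep
#'   (default 0 to 8% per year).
#' @return A data frame of parameter specs.
#' @export
make_param_specs <- function(params, config,
                             discount_range = c(0, 0.08)) {
  roles <- vapply(seq_len(nrow(params)), function(i) {
    param_role(params[i, ])
  }, character(1))
  specs <- data.frame(name = params$name, role = roles,
                      base = params$base, low = params$low,
                      high = params$high,
                      distribution = tolower(params$distribution),
                      psa = if ("psa" %in% names(params)) params$psa else TRUE,
                      stringsAsFactors = FALSE)
  specs$distribution[specs$distribution == "gamma1"] <- "gamma"
  rbind(specs,
        data.frame(name = "discount_rate", role = "config:discount_rate",
                   base = config$discount_rate_cost,
                   low = discount_range[1], high = discount_range[2],
                   distribution = "uniform", psa = FALSE,
                   stringsAsFactors = FALSE))
}

#' Build per-arm cost and utility sets from a parameter table
#'
#' @param params A parameter table.
#' @param arm `"sotorasib"` or `"docetaxel"`.
#' @return A list with elements `costs` ([cost_set()]) and `utilities`
#'   ([utility_set()]).
#' @export
build_arm_inputs <- function(params, arm) {
  pick <- function(category, arms = c(arm, "shared")) {
    params[params$category == category & params$arm %in% arms, ,
           drop = FALSE]
  }
  one <- function(name, default = 0) {
    row <- params[params$name == name, , drop = FALSE]
    if (nrow(row) == 0) default else row$base[1]
  }
  drug <- pick("drug", arm)
  if (nrow(drug) != 1) stop("expected one drug-cost row for arm ", arm)
  inc <- pick("ae_incidence", arm)
  aec <- pick("ae_cost", arm)
  aeu <- pick("ae_utility", arm)
  ae_events <- merge(inc[, c("event", "base")], aec[, c("event", "base")],
                     by = "event", suffixes = c("_inc", "_cost"))
  ae_dis <- merge(inc[, c("event", "base")], aeu[, c("event", "base")],
                  by = "event", suffixes = c("_inc", "_du"))
  costs <- cost_set(
    drug_cost_per_cycle = drug$base[1],
    followup_cost_per_cycle = one("C_followup"),
    hospitalization_cost_per_cycle = one("C_hospitalization"),
    bsc_cost_per_cycle = one("C_bestsupportive"),
    terminal_cost = one("C_terminal"),
    ae_events = data.frame(label = ae_events$event,
                           incidence = ae_events$base_inc,
                           unit_cost = ae_events$base_cost)
  )
  u <- pick("state_utility", "shared")
  utilities <- utility_set(
    u_pfs = u$base[u$event == "PFS"][1],
    u_pd = u$base[u$event == "PD"][1],
    ae_disutilities = data.frame(label = ae_dis$event,
                                 incidence = ae_dis$base_inc,
                                 disutility = ae_dis$base_du)
  )
  list(costs = costs, utilities = utilities)
}
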