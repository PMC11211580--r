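# One-way deterministic sensitivity analysis (tornado-ordered ICER
# ranges) and probabilistic sensitivity analysis via second-order Monte
# Carlo, with cost-effectiveness acceptability curves.

#' Build a reusable cost-effectiveness model closure
#'
#' Precomputes the cohort traces (which depend only on the survival fits
#' and cycle structure, not on costs, utilities or discounting) and
#' returns a function that evaluates both arms and their comparison under
#' a named list of parameter overrides. Override names are role strings
#' (see [make_param_specs()]), e.g. `"sotorasib:drug_cost_per_cycle"`,
#' `"shared:u_pfs"`, `"docetaxel:ae_cost:Neutropenia"` or
#' `"config:discount_rate"` (sets both cost and QALY rates).
#'
#' @param config A [model_config()].
#' @param intervention,comparator Lists with `costs`, `utilities`,
#'   `pfs_fit`, `os_fit` for each arm.
#' @param arm_names Length-2 character vector naming the arms as used in
#'   role strings.
#' @return A function `model(overrides = list())` returning a list with
#'   `intervention` and `comparator` (each `total_cost`, `total_qaly`)
#'   and `comparison` (a [compare_arms()] result).
#' @export
make_ce_model <- function(config, intervention, comparator,
                          arm_names = c("sotorasib", "docetaxel")) {
  stopifnot(inherits(config, "model_config"), length(arm_names) == 2)
  arms <- list(intervention, comparator)
  names(arms) <- arm_names
  traces <- lapply(arms, function(a) build_trace(config, a$pfs_fit, a$os_fit))

  function(overrides = list()) {
    cfg <- config
    local_arms <- arms
    for (role in names(overrides)) {
      value <- overrides[[role]]
      parts <- strsplit(role, ":", fixed = TRUE)[[1]]
      scope <- parts[1]
      if (scope == "config") {
        if (parts[2] != "discount_rate") stop("unknown config role: ", role)
        cfg$discount_rate_cost <- cfg$discount_rate_qaly <- value
        next
      }
      targets <- if (scope == "shared") arm_names else scope
      if (!all(targets %in% arm_names)) stop("unknown arm in role: ", role)
      for (a in targets) {
        if (length(parts) == 2) {
          field <- parts[2]
          if (field %in% c("u_pfs", "u_pd")) {
            local_arms[[a]]$utilities[[field]] <- value
          } else if (field %in% names(local_arms[[a]]$costs)) {
            local_arms[[a]]$costs[[field]] <- value
          } else stop("unknown field in role: ", role)
        } else if (length(parts) == 3) {
          kind <- parts[2]
          ev <- parts[3]
          key <- function(df) gsub(" ", "", df$label) == ev
          if (kind == "ae_cost") {
            i <- key(local_arms[[a]]$costs$ae_events)
            local_arms[[a]]$costs$ae_events$unit_cost[i] <- value
          } else if (kind == "ae_incidence") {
            i <- key(local_arms[[a]]$costs$ae_events)
            local_arms[[a]]$costs$ae_events$incidence[i] <- value
            j <- key(local_arms[[a]]$utilities$ae_disutilities)
            local_arms[[a]]$utilities$ae_disutilities$incidence[j] <- value
          } else if (kind == "ae_disutility") {
            j <- key(local_arms[[a]]$utilities$ae_disutilities)
            local_arms[[a]]$utilities$ae_disutilities$disutility[j] <- value
          } else stop("unknown role kind: ", role)
        } else stop("malformed role: ", role)
      }
    }
    res <- lapply(arm_names, function(a) {
      run_arm(cfg, local_arms[[a]]$costs, local_arms[[a]]$utilities,
              trace = traces[[a]])
    })
    names(res) <- c("intervention", "comparator")
    list(intervention = res$intervention, comparator = res$comparator,
         comparison = compare_arms(res$intervention, res$comparator))
  }
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each parameter to its low then high bound with all others at
#' base, records the resulting ICER, and sorts entries by ICER spread in
#' descending (tornado) order. A bound at which the comparison leaves
#' trade-off status (dominance) or the model fails yields an `NA` ICER
#' and a flagged entry, which sorts last; it is never dropped.
#'
#' @param specs A spec data frame from [make_param_specs()].
#' @param model A closure from [make_ce_model()].
#' @return An object of class `tornado`: data frame with columns name,
#'   role, low, high, icer_at_low, icer_at_high, spread, flagged.
#' @export
one_way <- function(specs, model) {
  icer_at <- function(role, value) {
    out <- tryCatch(model(stats::setNames(list(value), role)),
                    error = function(e) NULL)
    if (is.null(out) || out$comparison$status != "trade-off" ||
        !is.finite(out$comparison$icer)) NA_real_
    else out$comparison$icer
  }
  lo <- mapply(icer_at, specs$role, specs$low)
  hi <- mapply(icer_at, specs$role, specs$high)
  spread <- abs(hi - lo)
  out <- data.frame(name = specs$name, role = specs$role,
                    low = specs$low, high = specs$high,
                    icer_at_low = lo, icer_at_high = hi,
                    spread = spread, flagged = !is.finite(spread),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$spread, out$name, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Moment-match a sampling distribution to base/low/high
#'
#' The standard deviation is read off the bounds as (high - low)/(2 x
#' 1.96), i.e. treating them as a 95% interval. Beta parameters come from
#' mean/variance identities alpha = m(m(1-m)/s^2 - 1), beta = (1-m)(...);
#' gamma from shape = m^2/s^2, scale = s^2/m. When the beta identities
#' are infeasible (variance >= m(1-m), which includes any mean outside
#' (0, 1), e.g. a cost row labelled beta) the sampler falls back to
#' uniform(low, high) with a warning. Zero-width bounds give a
#' degenerate point mass.
#'
#' @param base,low,high Base value and bounds.
#' @param distribution `"beta"`, `"gamma"` or `"uniform"`.
#' @return A list with `distribution` (possibly the fallback), `params`,
#'   `mean`, `sd` and `fallback` flag.
#' @export
moment_match <- function(base, low, high, distribution) {
  distribution <- tolower(distribution)
  if (distribution == "gamma1") distribution <- "gamma"
  s <- (high - low) / (2 * 1.96)
  m <- base
  if (s == 0) {
    return(list(distribution = "degenerate", params = c(value = m),
                mean = m, sd = 0, fallback = FALSE))
  }
  if (distribution == "uniform") {
    return(list(distribution = "uniform", params = c(min = low, max = high),
                mean = (low + high) / 2, sd = (high - low) / sqrt(12),
                fallback = FALSE))
  }
  if (distribution == "beta") {
    if (m <= 0 || m >= 1 || s^2 >= m * (1 - m)) {
      warning(sprintf(
        "beta infeasible for mean %.4g, sd %.4g; falling back to uniform(%.4g, %.4g)",
        m, s, low, high))
      return(list(distribution = "uniform",
                  params = c(min = low, max = high),
                  mean = (low + high) / 2, sd = (high - low) / sqrt(12),
                  fallback = TRUE))
    }
    nu <- m * (1 - m) / s^2 - 1
    return(list(distribution = "beta",
                params = c(shape1 = m * nu, shape2 = (1 - m) * nu),
                mean = m, sd = s, fallback = FALSE))
  }
  if (distribution == "gamma") {
    if (m <= 0) stop("gamma requires a positive mean, got ", m)
    return(list(distribution = "gamma",
                params = c(shape = m^2 / s^2, scale = s^2 / m),
                mean = m, sd = s, fallback = FALSE))
  }
  stop("unknown distribution: ", distribution)
}

# Draw n values from a moment-matched distribution.
sample_moment_match <- function(mm, n) {
  switch(mm$distribution,
    degenerate = rep(mm$params[["value"]], n),
    uniform = stats::runif(n, mm$params[["min"]], mm$params[["max"]]),
    beta = stats::rbeta(n, mm$params[["shape1"]], mm$params[["shape2"]]),
    gamma = stats::rgamma(n, shape = mm$params[["shape"]],
                          scale = mm$params[["scale"]]),
    stop("unknown distribution: ", mm$distribution)
  )
}

# Deterministic per-parameter substream seed: a parameter's draws depend
# on the master seed and its own name only, so adding or removing another
# parameter does not perturb them.
param_substream_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483629
  as.integer((h + (seed %% 2147483629) * 65537) %% 2147483629) + 1L
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Samples every spec with `psa = TRUE` from its moment-matched
#' distribution (each parameter on its own deterministic substream of
#' the master seed) and re-evaluates both arms per draw with all
#' parameters sampled jointly. Survival-curve parameters are not
#' resampled: the probabilistic analysis varies cost and utility inputs
#' only.
#'
#' @param specs A spec data frame from [make_param_specs()].
#' @param model A closure from [make_ce_model()].
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Master seed.
#' @return An object of class `psa_run`: list with `n_draws`, `seed`,
#'   `draws` (n_draws x n_params matrix, columns named by role),
#'   `results` (per-draw cost/QALY per arm), `specs`, `n_failed`.
#' @export
run_psa <- function(specs, model, n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  specs <- specs[if ("psa" %in% names(specs)) specs$psa else TRUE, ,
                 drop = FALSE]
  if (nrow(specs) == 0) stop("no parameters flagged for PSA sampling")
  mms <- lapply(seq_len(nrow(specs)), function(i) {
    moment_match(specs$base[i], specs$low[i], specs$high[i],
                 specs$distribution[i])
  })
  draws <- matrix(NA_real_, nrow = n_draws, ncol = nrow(specs),
                  dimnames = list(NULL, specs$role))
  for (i in seq_len(nrow(specs))) {
    draws[, i] <- with_preserved_seed(
      param_substream_seed(seed, specs$name[i]),
      sample_moment_match(mms[[i]], n_draws)
    )
  }
  cols <- c("cost_intervention", "qaly_intervention",
            "cost_comparator", "qaly_comparator")
  results <- matrix(NA_real_, nrow = n_draws, ncol = 4,
                    dimnames = list(NULL, cols))
  n_failed <- 0L
  for (d in seq_len(n_draws)) {
    out <- tryCatch(model(as.list(draws[d, ])), error = function(e) NULL)
    if (is.null(out)) {
      n_failed <- n_failed + 1L
      next
    }
    results[d, ] <- c(out$intervention$total_cost,
                      out$intervention$total_qaly,
                      out$comparator$total_cost,
                      out$comparator$total_qaly)
  }
  if (n_failed > 0.01 * n_draws) {
    stop(n_failed, " of ", n_draws, " PSA draws failed (> 1%)")
  }
  structure(list(n_draws = as.integer(n_draws), seed = seed,
                 draws = draws, results = as.data.frame(results),
                 specs = specs, n_failed = n_failed),
            class = "psa_run")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is preferred is the fraction of draws with strictly
#' greater net monetary benefit; ties count to the comparator.
#'
#' @param psa A [run_psa()] result.
#' @param lambda_grid WTP grid (default 0 to 250,000 by 2,500).
#' @return A data frame with columns `lambda`, `p_intervention`,
#'   `p_comparator`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 250000, by = 2500)) {
  stopifnot(inherits(psa, "psa_run"))
  r <- psa$results[stats::complete.cases(psa$results), , drop = FALSE]
  if (nrow(r) == 0) stop("PSA run contains no successful draws")
  p <- vapply(lambda_grid, function(l) {
    mean(nmb(r$cost_intervention, r$qaly_intervention, l) >
           nmb(r$cost_comparator, r$qaly_comparator, l))
  }, numeric(1))
  data.frame(lambda = lambda_grid, p_intervention = p,
             p_comparator = 1 - p)
}

#' First WTP value at which the intervention reaches 50% acceptability
#'
#' @param points A [ceac()] table (>= 2 rows).
#' @return The smallest grid lambda with `p_intervention >= 0.5`, or
#'   `NA_real_` if the curve never reaches 0.5.
#' @export
ceac_crossover <- function(points) {
  stopifnot(nrow(points) >= 2)
  hit <- which(points$p_intervention >= 0.5)
  if (length(hit) == 0) NA_real_ else points$lambda[min(hit)]
}

#' @export
print.psa_run <- function(x, ...) {
  cat(sprintf("PSA run: %d draws (seed %s), %d parameters, %d failed\n",
              x$n_draws, format(x$seed), ncol(x$draws), x$n_failed))
  invisible(x)
}

#' @export
print.tornado <- function(x, ...) {
  cat("One-way sensitivity analysis (tornado order):\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
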