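# Run configuration, orchestration of the full analysis, and emission of
# all plot-ready result tables (base case, tornado, PSA plane, CEAC) plus
# a reproducibility manifest.

#' Run configuration with perspective presets
#'
#' Presets bundle the documented defaults per societal perspective:
#' `"china"` (per-capita GDP $12,374.81; exchange rate 6.92 RMB/USD; body
#' surface area 1.72 m^2; 5%/year discount) and `"us"` (GDP $76,348; BSA
#' 1.82 m^2; 3%/year discount). Every field can be overridden. The WTP
#' band is 1x and 3x GDP.
#'
#' @param perspective `"china"` or `"us"`.
#' @param seed Master seed for every source of randomness in the run.
#' @param ... Overrides for any field: `gdp_per_capita`,
#'   `wtp_multipliers`, `bsa_m2`, `n_draws`, `lambda_grid`,
#'   `curve_files` (named list of paths), `param_file`, plus any
#'   [model_config()] argument.
#' @return An object of class `run_config`.
#' @export
run_config <- function(perspective = c("china", "us"), seed = 1, ...) {
  perspective <- match.arg(perspective)
  preset <- if (perspective == "china") {
    list(gdp_per_capita = 12374.81, bsa_m2 = 1.72,
         discount_rate_cost = 0.05, discount_rate_qaly = 0.05,
         currency_per_usd = 6.92)
  } else {
    list(gdp_per_capita = 76348, bsa_m2 = 1.82,
         discount_rate_cost = 0.03, discount_rate_qaly = 0.03,
         currency_per_usd = 1)
  }
  cfg <- list(perspective = perspective, seed = seed,
              wtp_multipliers = c(1, 3), n_draws = 1000,
              lambda_grid = seq(0, 250000, by = 2500),
              curve_files = NULL, param_file = NULL,
              n_points = 40, noise_sd = 0.01)
  cfg <- utils::modifyList(cfg, preset)
  dots <- list(...)
  unknown <- setdiff(names(dots),
                     c(names(cfg), names(formals(model_config))))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  mc_args <- dots[intersect(names(dots), names(formals(model_config)))]
  mc_args$discount_rate_cost <- cfg$discount_rate_cost
  mc_args$discount_rate_qaly <- cfg$discount_rate_qaly
  mc_args$currency_per_usd <- cfg$currency_per_usd
  cfg$model <- do.call(model_config, mc_args)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with a `perspective` key and any [run_config()]
#'   overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  persp <- y$perspective %||% "china"
  seed <- y$seed %||% 1
  y$perspective <- NULL
  y$seed <- NULL
  do.call(run_config, c(list(perspective = persp, seed = seed), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load curves from configured files, or generate the synthetic bundle.
resolve_inputs <- function(config) {
  if (!is.null(config$curve_files)) {
    needed <- c("sotorasib_pfs", "docetaxel_pfs", "sotorasib_os",
                "docetaxel_os")
    missing <- setdiff(needed, names(config$curve_files))
    missing_files <- unlist(config$curve_files)[
      !file.exists(unlist(config$curve_files))]
    if (is.null(config$param_file) || !file.exists(config$param_file)) {
      missing_files <- c(missing_files, param_file = config$param_file)
    }
    if (length(missing) || length(missing_files)) {
      stop("configuration incomplete; missing curves: ",
           paste(missing, collapse = ", "), "; missing files: ",
           paste(missing_files, collapse = ", "))
    }
    curves <- lapply(needed, function(nm) {
      read_digitized_curve(config$curve_files[[nm]],
                           arm = sub("_(pfs|os)$", "", nm),
                           endpoint = toupper(sub("^.*_", "", nm)))
    })
    names(curves) <- needed
    list(curves = curves, params = read_param_table(config$param_file),
         synthetic = FALSE)
  } else {
    b <- trial_like_bundle(seed = config$seed,
                           perspective = config$perspective,
                           n_points = config$n_points,
                           noise_sd = config$noise_sd)
    list(curves = b$curves, params = b$params, synthetic = TRUE)
  }
}

#' Run the base-case cost-effectiveness analysis
#'
#' Fits all seven survival families to each of the four digitized curves
#' (both arms x PFS/OS), selects by AIC, checks endpoint coherence, runs
#' both arms through the partitioned-survival model, and assembles the
#' incremental comparison with its WTP interpretation. All resolved
#' defaults (cycle length, discount rates, half-cycle correction) are
#' recorded in the returned object.
#'
#' @param config A [run_config()].
#' @return An object of class `base_case`: list with `selections` (per
#'   curve), `coherence`, `arms` (named [run_arm()] results), `comparison`,
#'   `band`, `decision`, `table2` (the comparison report table),
#'   `aic_tables`, `params`, `resolved` (defaults in force).
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  selections <- lapply(inputs$curves, fit_all_families)
  fits <- lapply(selections, function(s) s$best_fit)

  grid <- seq(0.5, config$model$n_cycles *
                config$model$cycle_length_days / DAYS_PER_MONTH,
              by = 0.5)
  coherence <- list(
    sotorasib = enforce_endpoint_coherence(fits$sotorasib_os,
                                           fits$sotorasib_pfs, grid),
    docetaxel = enforce_endpoint_coherence(fits$docetaxel_os,
                                           fits$docetaxel_pfs, grid)
  )

  arm_in <- list(sotorasib = build_arm_inputs(inputs$params, "sotorasib"),
                 docetaxel = build_arm_inputs(inputs$params, "docetaxel"))
  arms <- list(
    sotorasib = run_arm(config$model, arm_in$sotorasib$costs,
                        arm_in$sotorasib$utilities,
                        fits$sotorasib_pfs, fits$sotorasib_os),
    docetaxel = run_arm(config$model, arm_in$docetaxel$costs,
                        arm_in$docetaxel$utilities,
                        fits$docetaxel_pfs, fits$docetaxel_os)
  )
  comparison <- compare_arms(arms$sotorasib, arms$docetaxel)
  band <- wtp_thresholds(config$gdp_per_capita, config$wtp_multipliers)
  decision <- interpret_icer(comparison, band)

  table2 <- data.frame(
    result = c("Cost", "Incr Cost", "QALYs", "Incr QALY", "ICER"),
    sotorasib = c(arms$sotorasib$total_cost, comparison$delta_cost,
                  arms$sotorasib$total_qaly, comparison$delta_qaly,
                  comparison$icer),
    docetaxel = c(arms$docetaxel$total_cost, NA, arms$docetaxel$total_qaly,
                  NA, NA)
  )
  structure(list(
    selections = selections, fits = fits, coherence = coherence,
    arm_inputs = arm_in, arms = arms, comparison = comparison,
    band = band, decision = decision, table2 = table2,
    aic_tables = lapply(selections, function(s) s$table),
    params = inputs$params, synthetic_inputs = inputs$synthetic,
    resolved = list(
      cycle_length_days = config$model$cycle_length_days,
      n_cycles = config$model$n_cycles,
      discount_rate_cost = config$model$discount_rate_cost,
      discount_rate_qaly = config$model$discount_rate_qaly,
      half_cycle_correction = config$model$half_cycle_correction,
      apply_ae_disutility = config$model$apply_ae_disutility,
      perspective = config$perspective, seed = config$seed
    )
  ), class = "base_case")
}

#' Run the full analysis: base case, tornado, PSA and CEAC
#'
#' One invocation produces every result table. When `out_dir` is given,
#' artifacts are written as delimited text plus a JSON manifest recording
#' the seed, a configuration hash and the package version. Stages run
#' under a partial-failure policy: completed artifacts are kept and
#' failures enumerated in `$errors`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `full_run`: list with `base`, `tornado`,
#'   `psa`, `ceac`, `crossover`, `manifest`, `errors`.
#' @export
run_full <- function(config, out_dir = NULL) {
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  base <- stage("base_case", run_base_case(config))
  tornado <- psa <- ceac_tab <- crossover <- NULL
  if (!is.null(base)) {
    model <- make_ce_model(
      config$model,
      intervention = c(base$arm_inputs$sotorasib,
                       list(pfs_fit = base$fits$sotorasib_pfs,
                            os_fit = base$fits$sotorasib_os)),
      comparator = c(base$arm_inputs$docetaxel,
                     list(pfs_fit = base$fits$docetaxel_pfs,
                          os_fit = base$fits$docetaxel_os))
    )
    specs <- make_param_specs(base$params, config$model)
    tornado <- stage("tornado", one_way(specs, model))
    psa <- stage("psa", run_psa(specs, model, n_draws = config$n_draws,
                                seed = config$seed))
    if (!is.null(psa)) {
      ceac_tab <- stage("ceac", ceac(psa, config$lambda_grid))
      if (!is.null(ceac_tab)) crossover <- ceac_crossover(ceac_tab)
    }
  }
  manifest <- list(
    seed = config$seed,
    perspective = config$perspective,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("psmcea")),
    n_draws = config$n_draws,
    completed = c("base_case", "tornado", "psa", "ceac")[
      !vapply(list(base, tornado, psa, ceac_tab), is.null, logical(1))],
    errors = errors
  )
  out <- structure(list(base = base, tornado = tornado, psa = psa,
                        ceac = ceac_tab, crossover = crossover,
                        manifest = manifest, errors = errors),
                   class = "full_run")
  if (!is.null(out_dir)) write_full_run(out, config, out_dir)
  out
}

# Write every artifact of a full run as delimited text + JSON manifest.
write_full_run <- function(run, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$base)) {
    wt(run$base$table2, "base_case.tsv")
    for (nm in names(run$base$selections)) {
      wt(fit_report(run$base$selections[[nm]]),
         paste0("fit_report_", nm, ".tsv"))
    }
    for (arm in names(run$base$arms)) {
      write_trace(run$base$arms[[arm]], config$model,
                  run$base$arm_inputs[[arm]]$costs,
                  run$base$arm_inputs[[arm]]$utilities,
                  file.path(out_dir, paste0("trace_", arm, ".tsv")))
    }
  }
  if (!is.null(run$tornado)) wt(as.data.frame(run$tornado), "tornado.tsv")
  if (!is.null(run$psa)) {
    wt(cbind(draw = seq_len(run$psa$n_draws),
             as.data.frame(run$psa$draws), run$psa$results), "psa.tsv")
  }
  if (!is.null(run$ceac)) {
    ce <- run$ceac
    names(ce) <- c("lambda", "p_sotorasib", "p_docetaxel")
    wt(ce, "ceac.tsv")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# FNV-1a-style hash of the deparsed configuration (hex string). Stable
# across sessions for identical configs.
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.base_case <- function(x, ...) {
  cat(sprintf("Base case (%s perspective):\n", x$resolved$perspective))
  t2 <- x$table2
  t2$sotorasib <- round(t2$sotorasib, 2)
  t2$docetaxel <- round(t2$docetaxel, 2)
  print(t2, row.names = FALSE)
  cat("Selected families:",
      paste(sprintf("%s=%s", names(x$selections),
                    vapply(x$selections, function(s) s$best, character(1))),
            collapse = ", "), "\n")
  cat(sprintf("WTP band: $%.2f - $%.2f per QALY; decision: %s\n",
              x$band$thresholds[1], x$band$thresholds[length(x$band$thresholds)],
              x$decision))
  invisible(x)
}

#' @export
print.full_run <- function(x, ...) {
  cat("Full analysis run\n")
  if (!is.null(x$base)) print(x$base)
  if (!is.null(x$tornado)) {
    cat("\nTop tornado drivers:\n")
    print(utils::head(as.data.frame(x$tornado)[, c("name", "icer_at_low",
                                                   "icer_at_high", "spread")],
                      5), row.names = FALSE)
  }
  if (!is.null(x$crossover)) {
    cat(sprintf("\nCEAC 50%% crossover: %s\n",
                if (is.na(x$crossover)) "not reached"
                else sprintf("$%.0f per QALY", x$crossover)))
  }
  if (length(x$errors)) {
    cat("Failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
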