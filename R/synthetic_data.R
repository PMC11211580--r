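# Synthetic digitized KM curves and parameter tables with the statistical
# structure the analysis assumes, so every pipeline stage is testable
# without external data. PFS curves are lognormals calibrated exactly to
# the trial's published summaries (median 5.6 vs 4.5 months; 12-month PFS
# 24.8% vs 10.1%); OS summaries are not available in the source text, so
# OS curves are synthetic stand-ins (medians 10.65 and 11.3 months)
# sharing each arm's PFS sdlog, which guarantees S_OS >= S_PFS
# everywhere.

#' Calibrate a lognormal survival curve to a median and one landmark
#'
#' Solves for (mu, sigma) such that S(median) = 0.5 and S(t) = s_at_t:
#' mu = ln(median), sigma = (ln t - mu) / z with z the standard-normal
#' quantile of 1 - s_at_t. The resulting curve reproduces both summaries
#' exactly. Requires a feasible pair: the landmark must lie beyond the
#' median with survival strictly between 0 and 0.5.
#'
#' @param median Median survival in months (> 0).
#' @param s_at_t Survival probability at the landmark time, in (0, 0.5).
#' @param t Landmark time in months (> median).
#' @return A lognormal [parametric_fit()] (rss/aic NA: calibrated, not
#'   fitted).
#' @export
lognormal_from_summaries <- function(median, s_at_t, t) {
  if (median <= 0 || t <= median) {
    stop("landmark time must exceed the (positive) median")
  }
  if (s_at_t <= 0 || s_at_t >= 0.5) {
    stop("landmark survival must lie strictly between 0 and 0.5 ",
         "when t > median (got ", s_at_t, ")")
  }
  mu <- log(median)
  z <- stats::qnorm(1 - s_at_t)
  sigma <- (log(t) - mu) / z
  parametric_fit("lognormal", c(meanlog = mu, sdlog = sigma))
}

#' Recipe for generating a synthetic digitized curve
#'
#' @param family Generating family, one of [survival_families()].
#' @param params Named family parameters.
#' @param n_points Number of digitized points (>= 5, default 40).
#' @param t_max Last time point in months (> 0).
#' @param noise_sd Additive Gaussian digitization noise on the survival
#'   scale (>= 0).
#' @param seed RNG seed.
#' @return An object of class `curve_recipe`.
#' @export
curve_recipe <- function(family, params, n_points = 40, t_max = 18,
                         noise_sd = 0.01, seed = 1) {
  family <- match.arg(family, survival_families())
  stopifnot(n_points >= 5, t_max > 0, noise_sd >= 0)
  structure(list(family = family, params = params,
                 n_points = as.integer(n_points), t_max = t_max,
                 noise_sd = noise_sd, seed = seed),
            class = "curve_recipe")
}

#' Generate synthetic digitized KM points from a recipe
#'
#' Points are evenly spaced on (0, t_max\]. Digitization error is
#' additive Gaussian noise on the survival scale, after which values are
#' clamped to \[0, 1\] and monotonized by running minimum (a digitized KM
#' curve can never increase). Reproducible given the recipe's seed.
#'
#' @param recipe A [curve_recipe()].
#' @param arm,endpoint Labels for the resulting curve.
#' @return A [digitized_curve()].
#' @export
generate_km_points <- function(recipe, arm = "synthetic",
                               endpoint = "synthetic") {
  stopifnot(inherits(recipe, "curve_recipe"))
  time <- seq(recipe$t_max / recipe$n_points, recipe$t_max,
              length.out = recipe$n_points)
  s <- family_survival(recipe$family, recipe$params, time)
  if (recipe$noise_sd > 0) {
    s <- s + with_preserved_seed(recipe$seed,
                                 stats::rnorm(length(s),
                                              sd = recipe$noise_sd))
  }
  s <- cummin(pmin(pmax(s, 0), 1))
  digitized_curve(time, s, arm = arm, endpoint = endpoint)
}

#' Trial-like synthetic workspace: four curves plus a parameter table
#'
#' Generates sotorasib/docetaxel PFS and OS digitized curves together
#' with the perspective's parameter table. PFS curves are calibrated to
#' the published medians and 12-month rates; OS curves are synthetic
#' stand-ins coherent with PFS by construction (see the module header).
#'
#' @param seed Master seed; the four curves use distinct derived
#'   substreams.
#' @param perspective `"china"` or `"us"` (selects the parameter table).
#' @param n_points Digitized points per curve (default 40).
#' @param noise_sd Digitization noise (default 0.01).
#' @param pfs_t_max,os_t_max Time grids in months (defaults 18 and 24).
#' @return A list with `curves` (named list of four
#'   [digitized_curve()]s), `true_fits` (the generating
#'   [parametric_fit()]s), `params` (the [param_table()]) and
#'   `calibration` (the summary statistics used).
#' @export
trial_like_bundle <- function(seed = 1, perspective = "china",
                              n_points = 40, noise_sd = 0.01,
                              pfs_t_max = 18, os_t_max = 24) {
  calibration <- list(
    sotorasib_pfs = list(median = 5.6, s12 = 0.248),
    docetaxel_pfs = list(median = 4.5, s12 = 0.101),
    sotorasib_os = list(median = 10.65, synthetic = TRUE),
    docetaxel_os = list(median = 11.3, synthetic = TRUE)
  )
  pfs_s <- lognormal_from_summaries(5.6, 0.248, 12)
  pfs_d <- lognormal_from_summaries(4.5, 0.101, 12)
  # OS: same sdlog as the arm's PFS, larger meanlog => coherent
  os_s <- parametric_fit("lognormal",
                         c(meanlog = log(10.65),
                           sdlog = pfs_s$params[["sdlog"]]))
  os_d <- parametric_fit("lognormal",
                         c(meanlog = log(11.3),
                           sdlog = pfs_d$params[["sdlog"]]))
  true_fits <- list(sotorasib_pfs = pfs_s, docetaxel_pfs = pfs_d,
                    sotorasib_os = os_s, docetaxel_os = os_d)
  tmax <- c(sotorasib_pfs = pfs_t_max, docetaxel_pfs = pfs_t_max,
            sotorasib_os = os_t_max, docetaxel_os = os_t_max)
  curves <- lapply(seq_along(true_fits), function(i) {
    nm <- names(true_fits)[i]
    rec <- curve_recipe("lognormal", true_fits[[i]]$params,
                        n_points = n_points, t_max = tmax[[nm]],
                        noise_sd = noise_sd,
                        seed = (seed %% 536870912L) * 4L + i)
    generate_km_points(rec,
                       arm = sub("_(pfs|os)$", "", nm),
                       endpoint = toupper(sub("^.*_", "", nm)))
  })
  names(curves) <- names(true_fits)
  list(curves = curves, true_fits = true_fits,
       params = param_table(perspective), calibration = calibration)
}

#' Write a ready-to-run synthetic workspace to disk
#'
#' Emits the four digitized-curve files and the parameter table in the
#' same delimited formats the fitting and cohort modules consume.
#'
#' @param bundle A [trial_like_bundle()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (nm in names(bundle$curves)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_digitized_curve(bundle$curves[[nm]], p)
    paths[nm] <- p
  }
  pt <- file.path(dir, "parameters.tsv")
  write_param_table(bundle$params, pt)
  paths["parameters"] <- pt
  invisible(paths)
}
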