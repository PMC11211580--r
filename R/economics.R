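# Incremental cost-effectiveness comparison, willingness-to-pay bands
# from GDP multiples, net monetary benefit, and decision interpretation.

#' Incremental cost-effectiveness comparison of two arms
#'
#' Deltas are intervention minus comparator. The intervention is
#' *dominant* if it is cheaper and more effective, *dominated* if costlier
#' and less effective; otherwise the comparison is a trade-off with
#' ICER = delta cost / delta QALY. A trade-off with zero QALY gain and a
#' non-zero cost difference yields a signed-infinite ICER marker.
#'
#' @param intervention,comparator [run_arm()] results, or any lists with
#'   finite `total_cost` and `total_qaly`.
#' @return An object of class `ce_comparison`: list with `delta_cost`,
#'   `delta_qaly`, `icer` (NA unless trade-off) and `status` (one of
#'   `"dominant"`, `"dominated"`, `"trade-off"`).
#' @export
compare_arms <- function(intervention, comparator) {
  vals <- c(intervention$total_cost, intervention$total_qaly,
            comparator$total_cost, comparator$total_qaly)
  if (!all(is.finite(vals))) stop("arm results must be finite")
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  if (dc < 0 && de > 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (dc > 0 && de < 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "trade-off"
    icer <- if (de == 0) {
      if (dc == 0) 0 else sign(dc) * Inf
    } else dc / de
  }
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer,
                 status = status),
            class = "ce_comparison")
}

#' Willingness-to-pay thresholds from per-capita GDP multiples
#'
#' Thresholds are exact (unrounded) products gdp x multipliers; the
#' conventional band is 1x and 3x per-capita GDP.
#'
#' @param gdp_per_capita Per-capita GDP in USD (> 0).
#' @param multipliers Ordered positive multipliers (default `c(1, 3)`).
#' @return An object of class `wtp_band` with `gdp_per_capita`,
#'   `multipliers`, `thresholds`.
#' @export
wtp_thresholds <- function(gdp_per_capita, multipliers = c(1, 3)) {
  if (gdp_per_capita <= 0) stop("per-capita GDP must be positive")
  if (any(multipliers <= 0) || any(diff(multipliers) <= 0)) {
    stop("multipliers must be positive and strictly increasing")
  }
  structure(list(gdp_per_capita = gdp_per_capita,
                 multipliers = multipliers,
                 thresholds = gdp_per_capita * multipliers),
            class = "wtp_band")
}

#' Net monetary benefit
#'
#' @param cost Total cost.
#' @param qaly Total QALYs.
#' @param lambda Willingness-to-pay threshold in money per QALY (>= 0).
#' @return lambda x qaly - cost; vectorised over any argument.
#' @export
nmb <- function(cost, qaly, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  lambda * qaly - cost
}

#' Interpret a comparison against a WTP band
#'
#' Trade-off ICERs (with a QALY gain) classify as `"cost-effective"` at
#' or below 1x GDP, `"acceptable"` at or below 3x GDP, else
#' `"not cost-effective"`; a value exactly at a boundary falls in the
#' more favourable category. Dominance statuses map directly. A
#' trade-off with a QALY loss and cost saving is judged by the reversed
#' rule: the saving per QALY forgone must exceed the top threshold.
#'
#' @param comparison A [compare_arms()] result.
#' @param band A [wtp_thresholds()] band with multipliers (1, 3).
#' @return A decision label (character scalar).
#' @export
interpret_icer <- function(comparison, band) {
  stopifnot(inherits(comparison, "ce_comparison"),
            inherits(band, "wtp_band"))
  if (comparison$status == "dominant") return("dominant (cost-effective)")
  if (comparison$status == "dominated") return("dominated (not cost-effective)")
  thr <- band$thresholds
  lo <- thr[1]; hi <- thr[length(thr)]
  if (comparison$delta_qaly >= 0) {
    if (comparison$icer <= lo) "cost-effective"
    else if (comparison$icer <= hi) "acceptable"
    else "not cost-effective"
  } else {
    # cheaper and less effective: cost saved per QALY forgone
    if (comparison$icer >= hi) "cost-effective" else "not cost-effective"
  }
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("Incremental comparison: delta cost $%.2f, delta QALY %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$status == "trade-off") {
    cat(sprintf("  ICER = $%.2f per QALY\n", x$icer))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}
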