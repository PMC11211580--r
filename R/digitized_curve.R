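#' Digitized Kaplan-Meier curve
#'
#' Container for (time, survival) coordinates extracted from a published
#' Kaplan-Meier plot for one arm and endpoint. Validates the invariants a
#' digitized survival curve must satisfy: strictly increasing times,
#' survival probabilities in \[0, 1\], non-increasing survival. Tiny upward
#' wobbles (at most 1e-9, e.g. from float round-trips) are clamped to the
#' running minimum; larger increases are rejected as digitization errors.
#'
#' @param time Numeric vector of times in months, strictly increasing, >= 0.
#' @param survival Numeric vector of survival probabilities in \[0, 1\].
#' @param arm Arm label, e.g. `"sotorasib"` or `"docetaxel"`.
#' @param endpoint Endpoint label, `"PFS"` or `"OS"`.
#'
#' @return An object of class `digitized_curve`: a data frame with columns
#'   `time_months` and `survival`, plus `arm`/`endpoint` attributes.
#' @export
digitized_curve <- function(time, survival, arm = "unknown",
                            endpoint = "unknown") {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival)) {
    stop("time and survival must have equal length")
  }
  if (length(time) < 2) stop("a digitized curve needs at least 2 points")
  if (anyNA(time) || anyNA(survival)) stop("missing values in curve points")
  if (any(time < 0)) stop("times must be non-negative")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(survival < 0 | survival > 1)) {
    stop("survival values must lie in [0, 1]")
  }
  up <- diff(survival)
  if (any(up > 1e-9)) {
    stop("survival values increase along the curve (digitization error)")
  }
  # clamp sub-1e-9 increases; plateaus are legitimate
  survival <- cummin(survival)
  out <- data.frame(time_months = time, survival = survival)
  attr(out, "arm") <- as.character(arm)
  attr(out, "endpoint") <- as.character(endpoint)
  class(out) <- c("digitized_curve", "data.frame")
  out
}

#' Read a digitized curve from a delimited text file
#'
#' Expects a header `time_months,survival` (comma- or tab-delimited), one
#' file per arm and endpoint.
#'
#' @param path File path.
#' @param arm,endpoint Labels attached to the curve.
#' @return A [digitized_curve()].
#' @export
read_digitized_curve <- function(path, arm = "unknown", endpoint = "unknown") {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_months", "survival")
  if (!all(need %in% names(df))) {
    stop("curve file must have columns time_months, survival: ", path)
  }
  digitized_curve(df$time_months, df$survival, arm = arm, endpoint = endpoint)
}

#' Write a digitized curve to a delimited text file
#'
#' @param curve A [digitized_curve()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_digitized_curve <- function(curve, path, sep = ",") {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.table(as.data.frame(curve)[, c("time_months", "survival")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve: %s / %s, %d points, t in [%.3g, %.3g] months\n",
              attr(x, "arm"), attr(x, "endpoint"), nrow(x),
              min(x$time_months), max(x$time_months)))
  invisible(x)
}
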