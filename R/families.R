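# Registry of the seven parametric survival families used to extrapolate
# digitized Kaplan-Meier curves. Each entry carries the family's free
# parameter names, its survival function, an unconstrained reparameterisation
# for the optimizer, and a moment-style initializer from digitized points.
#
# Parameterisations follow stats/flexsurv conventions:
#   exponential  rate                     S(t) = exp(-rate t)
#   weibull      shape, scale             S(t) = exp(-(t/scale)^shape)
#   gamma        shape, rate
#   gengamma     mu, sigma, Q             (Prentice form; Q = 0 is lognormal)
#   gompertz     shape, rate              (shape may be negative: plateaus)
#   lognormal    meanlog, sdlog           S(t) = 1 - Phi((ln t - mu)/sigma)
#   loglogistic  shape, scale

#' Supported parametric survival families
#'
#' Fixed family order; also the deterministic tie-break order for AIC
#' selection (after preferring fewer parameters).
#'
#' @return Character vector of family labels.
#' @export
survival_families <- function() {
  c("exponential", "weibull", "gamma", "gengamma", "gompertz",
    "lognormal", "loglogistic")
}

# Number of free parameters per family.
family_k <- function(family) {
  switch(family,
    exponential = 1L,
    weibull = 2L, gamma = 2L, gompertz = 2L, lognormal = 2L,
    loglogistic = 2L,
    gengamma = 3L,
    stop("unknown survival family: ", family)
  )
}

family_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gamma = c("shape", "rate"),
    gengamma = c("mu", "sigma", "Q"),
    gompertz = c("shape", "rate"),
    lognormal = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    stop("unknown survival family: ", family)
  )
}

# Survival function S(t; params) for one family; vectorised over t.
family_survival <- function(family, params, t) {
  p <- as.list(params)
  switch(family,
    exponential = exp(-p$rate * t),
    weibull = stats::pweibull(t, shape = p$shape, scale = p$scale,
                              lower.tail = FALSE),
    gamma = stats::pgamma(t, shape = p$shape, rate = p$rate,
                          lower.tail = FALSE),
    gengamma = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma, Q = p$Q,
                                   lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                   lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                              lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale,
                                    lower.tail = FALSE),
    stop("unknown survival family: ", family)
  )
}

# Map a named parameter vector to the optimizer's unconstrained scale and
# back. Positive parameters are log-transformed; location-like parameters
# (lognormal meanlog, gengamma mu/Q, gompertz shape) stay as-is.
family_to_unconstrained <- function(family, params) {
  p <- as.numeric(params)
  switch(family,
    exponential = log(p),
    weibull = log(p),
    gamma = log(p),
    gengamma = c(p[1], log(p[2]), p[3]),
    gompertz = c(p[1], log(p[2])),
    lognormal = c(p[1], log(p[2])),
    loglogistic = log(p),
    stop("unknown survival family: ", family)
  )
}

family_from_unconstrained <- function(family, theta) {
  p <- switch(family,
    exponential = exp(theta),
    weibull = exp(theta),
    gamma = exp(theta),
    gengamma = c(theta[1], exp(theta[2]), theta[3]),
    gompertz = c(theta[1], exp(theta[2])),
    lognormal = c(theta[1], exp(theta[2])),
    loglogistic = exp(theta),
    stop("unknown survival family: ", family)
  )
  stats::setNames(p, family_param_names(family))
}

# Moment-style starting values from digitized (time, survival) points.
# Interior points (0 < s < 1) feed simple linearising regressions; the
# time at survival closest to 0.5 anchors scale-like parameters.
family_init <- function(family, time, surv) {
  eps <- 1e-6
  s <- pmin(pmax(surv, eps), 1 - eps)
  interior <- time > 0
  tt <- time[interior]
  ss <- s[interior]
  t50 <- tt[which.min(abs(ss - 0.5))]
  if (t50 <= 0) t50 <- max(tt) / 2

  # regression of a linearised survival transform on (log-)time
  lin_fit <- function(y, x) {
    cf <- stats::coef(stats::lm(y ~ x))
    if (!all(is.finite(cf))) cf <- c(0, 1)
    cf
  }

  switch(family,
    exponential = {
      # log S = -rate * t, through the origin
      rate <- max(-sum(log(ss) * tt) / sum(tt^2), 1e-6)
      c(rate = rate)
    },
    weibull = {
      cf <- lin_fit(log(-log(ss)), log(tt))
      shape <- max(cf[2], 0.05)
      scale <- exp(-cf[1] / shape)
      c(shape = shape, scale = max(scale, 1e-3))
    },
    gamma = {
      cf <- lin_fit(log(-log(ss)), log(tt))
      shape <- max(cf[2], 0.1)
      c(shape = shape, rate = max(shape / t50, 1e-6))
    },
    gengamma = {
      cf <- lin_fit(stats::qnorm(1 - ss), log(tt))
      sigma <- max(1 / abs(cf[2]), 1e-3)
      c(mu = -cf[1] / cf[2], sigma = sigma, Q = 0)
    },
    gompertz = {
      rate <- max(-sum(log(ss) * tt) / sum(tt^2), 1e-6)
      c(shape = 0.01, rate = rate)
    },
    lognormal = {
      # qnorm(1 - S) = (log t - mu) / sigma
      cf <- lin_fit(stats::qnorm(1 - ss), log(tt))
      sigma <- max(1 / abs(cf[2]), 1e-3)
      c(meanlog = -cf[1] / cf[2], sdlog = sigma)
    },
    loglogistic = {
      # log((1 - S)/S) = shape (log t - log scale)
      cf <- lin_fit(log((1 - ss) / ss), log(tt))
      shape <- max(cf[2], 0.05)
      c(shape = shape, scale = max(exp(-cf[1] / shape), 1e-3))
    },
    stop("unknown survival family: ", family)
  )
}

# Run code with the global RNG stream untouched.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
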