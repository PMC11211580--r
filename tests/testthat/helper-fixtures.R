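# Shared fixtures: quick fit constructors, random valid family
# parameters for property-style loops, and a tiny two-arm model setup.

exp_fit <- function(rate) parametric_fit("exponential", c(rate = rate))

lnorm_fit <- function(meanlog, sdlog) {
  parametric_fit("lognormal", c(meanlog = meanlog, sdlog = sdlog))
}

# A plausible random parameter vector for each family (seeded by caller).
random_family_params <- function(family) {
  switch(family,
    exponential = c(rate = runif(1, 0.02, 0.5)),
    weibull = c(shape = runif(1, 0.5, 2.5), scale = runif(1, 2, 15)),
    gamma = c(shape = runif(1, 0.5, 3), rate = runif(1, 0.05, 0.6)),
    gengamma = c(mu = runif(1, 0.5, 2.5), sigma = runif(1, 0.4, 1.5),
                 Q = runif(1, -1, 1.5)),
    gompertz = c(shape = runif(1, -0.05, 0.2), rate = runif(1, 0.02, 0.3)),
    lognormal = c(meanlog = runif(1, 0.5, 2.5), sdlog = runif(1, 0.3, 1.5)),
    loglogistic = c(shape = runif(1, 0.8, 3), scale = runif(1, 2, 15))
  )
}

# Minimal two-arm model: identical exponential PFS/OS shapes per arm,
# simple costs/utilities; intervention is the costlier, more effective arm.
tiny_model_setup <- function(drug_int = 1000, drug_comp = 100,
                             rate_int = 0.08, rate_comp = 0.12,
                             discount = 0.05) {
  config <- model_config(n_cycles = 60, discount_rate_cost = discount,
                         discount_rate_qaly = discount)
  ae <- data.frame(label = "Diarrhoea", incidence = 0.1, unit_cost = 1200)
  aeu <- data.frame(label = "Diarrhoea", incidence = 0.1, disutility = 0.2)
  mk_arm <- function(drug, rate) {
    list(costs = cost_set(drug_cost_per_cycle = drug,
                          followup_cost_per_cycle = 50,
                          bsc_cost_per_cycle = 200, terminal_cost = 5000,
                          ae_events = ae),
         utilities = utility_set(0.8, 0.3, ae_disutilities = aeu),
         pfs_fit = exp_fit(rate * 1.5), os_fit = exp_fit(rate))
  }
  list(config = config,
       intervention = mk_arm(drug_int, rate_int),
       comparator = mk_arm(drug_comp, rate_comp))
}

tiny_specs <- function(setup) {
  data.frame(
    name = c("C_drug_int", "C_bsc", "U_PFS", "U_AE_int"),
    role = c("sotorasib:drug_cost_per_cycle", "shared:bsc_cost_per_cycle",
             "shared:u_pfs", "sotorasib:ae_disutility:Diarrhoea"),
    base = c(1000, 200, 0.8, 0.2),
    low = c(800, 160, 0.64, 0.16),
    high = c(1200, 240, 0.96, 0.24),
    distribution = c("gamma", "gamma", "beta", "beta"),
    psa = TRUE, stringsAsFactors = FALSE
  )
}
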