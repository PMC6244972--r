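# Independent oracles used across the suite.  These deliberately avoid the
# package's own solution paths: closed forms, quadrature, and brute-force
# Monte Carlo.

# Closed-form bolus solution of the linear two-compartment model (Vmax = 0):
# C(t) = dose/V1 * [ (alpha - k21)/(alpha - beta) e^{-alpha t}
#                  + (k21 - beta)/(alpha - beta) e^{-beta t} ]
biexp_conc <- function(params, dose, times) {
  k10 <- params$CL / params$V1
  k12 <- params$Q / params$V1
  k21 <- params$Q / params$V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  (dose / params$V1) * ((alpha - k21) / (alpha - beta) * exp(-alpha * times) +
                          (k21 - beta) / (alpha - beta) * exp(-beta * times))
}

# Brute-force Gauss-Hermite marginal -2LL for a PK subject with lognormal
# random effects on CL and V1 and combined residual error.
gh_m2ll_subject <- function(anchor, subj, omega_cv, residual, n_nodes = 32) {
  gh <- pracma::gaussHermite(n_nodes)
  sd1 <- sqrt(log(1 + (omega_cv[1] / 100)^2))
  sd2 <- sqrt(log(1 + (omega_cv[2] / 100)^2))
  lik <- 0
  for (i in seq_len(n_nodes)) {
    eta1 <- sqrt(2) * sd1 * gh$x[i]
    for (j in seq_len(n_nodes)) {
      eta2 <- sqrt(2) * sd2 * gh$x[j]
      p <- scale_params(anchor, subj$wt)
      p$CL <- p$CL * exp(eta1)
      p$V1 <- p$V1 * exp(eta2)
      f <- simulate_pk(p, regimen(subj$dose_times, subj$dose_amounts),
                       subj$obs_times)$conc
      v <- (residual$proportional_sd * f)^2 + residual$additive_sd^2
      lik <- lik + gh$w[i] * gh$w[j] *
        prod(stats::dnorm(subj$dv, f, sqrt(v)))
    }
  }
  -2 * log(lik / pi)
}

# Geometric mean (= exp of the mean log) of a lognormal distribution with
# the given median and CV, truncated to [lo, hi]: the quantity a lognormal
# location estimate is consistent for when the data come from the truncated
# distribution.
truncated_lognormal_gm <- function(median_, cv_percent, lo, hi) {
  sdlog <- sqrt(log(1 + (cv_percent / 100)^2))
  a <- (log(lo) - log(median_)) / sdlog
  b <- (log(hi) - log(median_)) / sdlog
  ez <- (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  exp(log(median_) + sdlog * ez)
}

# Small long-format PK dataset built by hand (two subjects, one dose level
# each) for likelihood unit tests.
toy_pk_dataset <- function(truth = human_default_params(),
                           doses = c(30, 90),
                           times = c(1, 24, 168, 504),
                           wt = 70, sigma_prop = 0.1, seed = 99) {
  set.seed(seed)
  rows <- lapply(seq_along(doses), function(i) {
    f <- simulate_pk(truth, regimen(0, doses[i]), times)$conc
    dv <- f * (1 + rnorm(length(f), 0, sigma_prop))
    rbind(data.frame(ID = i, TIME = 0, AMT = doses[i], DV = NA_real_,
                     EVID = 1, MDV = 1, CMT = 1, WT = wt,
                     DOSEGRP = doses[i] / wt, BLQ = 0),
          data.frame(ID = i, TIME = times, AMT = NA_real_, DV = dv,
                     EVID = 0, MDV = 0, CMT = 1, WT = wt,
                     DOSEGRP = doses[i] / wt, BLQ = 0))
  })
  do.call(rbind, rows)
}
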