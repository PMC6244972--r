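h <- human_default_params()

test_that("with no random effects the likelihood is the exact Gaussian one", {
  d <- toy_pk_dataset()
  res <- residual_spec(0.1, 0)
  got <- loglik(h, d, omega_spec(), res)
  # direct closed-form evaluation
  direct <- 0
  for (id in unique(d$ID)) {
    s <- d[d$ID == id, ]
    obs <- s[s$EVID == 0, ]
    f <- simulate_pk(h, regimen(s$TIME[s$EVID == 1], s$AMT[s$EVID == 1]),
                     obs$TIME)$conc
    v <- (0.1 * f)^2
    direct <- direct + sum(log(2 * pi * v) + (obs$DV - f)^2 / v)
  }
  expect_equal(got, direct, tolerance = 1e-10)
  # duplicating every observation doubles the data contribution
  d2 <- rbind(d, d[d$EVID == 0, ])
  d2 <- d2[order(d2$ID, d2$TIME, -d2$EVID), ]
  expect_equal(loglik(h, d2, omega_spec(), res), 2 * direct,
               tolerance = 1e-10)
})

test_that("the Laplace marginal likelihood agrees with quadrature", {
  skip_if_not_installed("pracma")
  d <- toy_pk_dataset(times = c(24, 168, 336, 504))
  om <- pk_omega_defaults()
  res <- pk_residual_defaults()
  lap <- loglik(h, d, om, res, method = "laplace")
  subs <- transpkpd:::.split_subjects(d)
  gh <- sum(vapply(subs, function(s) {
    gh_m2ll_subject(h, s, unclass(om), res)
  }, numeric(1)))
  expect_lt(abs(lap - gh), 0.1)
})

test_that("likelihood is invariant to a change of time units", {
  d <- toy_pk_dataset()
  res <- residual_spec(0.1, 0)
  base <- loglik(h, d, omega_spec(), res)
  # rescale hours -> days together with the rate parameters
  d_days <- d
  d_days$TIME <- d_days$TIME / 24
  h_days <- h
  for (nm in c("CL", "Q", "Vmax")) h_days[[nm]] <- h_days[[nm]] * 24
  expect_equal(loglik(h_days, d_days, omega_spec(), res), base,
               tolerance = 1e-6)
})

test_that("a noise-free rich dataset is recovered almost exactly", {
  truth <- pk_params(CL = 0.015, V1 = 2.8, Q = 0.04, V2 = 4, Vmax = 0.45,
                     Km = 0.219, body_weight = 70)
  times <- c(1, 4, 12, 24, 48, 96, 168, 336, 504, 672, 840, 1007)
  rows <- lapply(1:3, function(i) {
    dose <- c(30, 200, 1000)[i]
    f <- simulate_pk(truth, regimen(0, dose), times,
                     rtol = 1e-10, atol = 1e-12)$conc
    rbind(data.frame(ID = i, TIME = 0, AMT = dose, DV = NA_real_, EVID = 1,
                     MDV = 1, CMT = 1, WT = 70, DOSEGRP = dose, BLQ = 0),
          data.frame(ID = i, TIME = times, AMT = NA_real_, DV = f, EVID = 0,
                     MDV = 0, CMT = 1, WT = 70, DOSEGRP = dose, BLQ = 0))
  })
  d <- do.call(rbind, rows)
  init <- pk_params(CL = 0.01, V1 = 3.2, Q = 0.03, V2 = 3, Vmax = 0.6,
                    Km = 0.3, body_weight = 70)
  fit <- fit_pk(d, init = init, omega_init = omega_spec(),
                residual_init = residual_spec(0.01, 0),
                fix = c("sigma_prop", "sigma_add"), method = "fo",
                control = list(rel.tol = 1e-14, eval.max = 2000,
                               iter.max = 1000),
                sim_rtol = 1e-10, sim_atol = 1e-12)
  for (nm in c("CL", "V1", "Q", "V2", "Vmax", "Km")) {
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 1e-3)
  }
})

test_that("far below Km only the ratio Vmax/Km is identified", {
  truth <- human_default_params()
  times <- c(1, 4, 12, 24, 48, 96, 168, 240)
  rows <- lapply(1:2, function(i) {
    dose <- c(0.001, 0.004)[i]  # concentrations far below Km
    f <- simulate_pk(truth, regimen(0, dose), times,
                     rtol = 1e-12, atol = 1e-16)$conc
    rbind(data.frame(ID = i, TIME = 0, AMT = dose, DV = NA_real_, EVID = 1,
                     MDV = 1, CMT = 1, WT = 70, DOSEGRP = dose, BLQ = 0),
          data.frame(ID = i, TIME = times, AMT = NA_real_, DV = f, EVID = 0,
                     MDV = 0, CMT = 1, WT = 70, DOSEGRP = dose, BLQ = 0))
  })
  d <- do.call(rbind, rows)
  # start Vmax and Km away from truth; CL fixed (only the total linear
  # clearance CL + Vmax/Km is identified in this regime)
  init <- truth; init$Vmax <- 1.2; init$Km <- 0.6
  fit <- fit_pk(d, init = init, omega_init = omega_spec(),
                residual_init = residual_spec(0.02, 0),
                fix = c("CL", "V1", "Q", "V2", "sigma_prop", "sigma_add"),
                method = "fo", control = list(rel.tol = 1e-12),
                sim_rtol = 1e-10, sim_atol = 1e-14)
  ratio_hat <- fit$estimates$Vmax / fit$estimates$Km
  expect_equal(ratio_hat, truth$Vmax / truth$Km, tolerance = 0.1)
  # unidentifiability of the individual parameters: rescaling Vmax and Km
  # together (same ratio) barely changes the likelihood, while changing
  # the ratio changes it drastically
  res <- residual_spec(0.02, 0)
  at <- function(vmax, km) {
    p <- fit$estimates; p$Vmax <- vmax; p$Km <- km
    loglik(p, d, omega_spec(), res)
  }
  m0 <- at(fit$estimates$Vmax, fit$estimates$Km)
  m_scaled <- at(2 * fit$estimates$Vmax, 2 * fit$estimates$Km)
  m_ratio <- at(2 * fit$estimates$Vmax, fit$estimates$Km)
  expect_lt(abs(m_scaled - m0), 1)
  expect_gt(m_ratio - m0, 10)
})

test_that("fitting never returns a worse objective than its start", {
  set.seed(4)
  d <- generate_monkey_pk_study(seed = 21)
  start <- loglik(h, d, pk_omega_defaults(), pk_residual_defaults(),
                  method = "fo")
  fit <- fit_pk(d, init = h, method = "fo", compute_rse = FALSE)
  expect_lte(fit$objective, start + 1e-6)
})

test_that("vehicle-only tumor data recover the growth parameters", {
  truth <- pd_params()
  mouse <- mouse_default_params()
  times <- seq(0, 1632, 72)
  f <- vehicle_tumor_volume(truth, times)
  d <- data.frame(ID = 1, TIME = times, AMT = NA_real_, DV = f, EVID = 0,
                  MDV = 0, CMT = 2, WT = 0.02, DOSEGRP = 0, BLQ = 0)
  d <- rbind(d, within(d, ID <- 2))
  init <- pd_params(Base = 150, KG = 0.5, KD = 0.004, Kio = 0.143,
                    EC50 = 2.6, EC50_KD = 1.02e-5, lam = 0.1)
  expect_warning(
    fit <- fit_pd(d, mouse, init = init, omega_init = omega_spec(),
                  residual_init = residual_spec(0.05, 0),
                  fix = c("KD", "Kio", "EC50", "EC50_KD", "sigma_prop"),
                  method = "fo", control = list(rel.tol = 1e-12)),
    NA)
  expect_equal(fit$estimates$Base, truth$Base, tolerance = 0.01)
  expect_equal(fit$estimates$KG, truth$KG, tolerance = 0.01)
  expect_equal(fit$estimates$lam, truth$lam, tolerance = 0.01)
  # drug-effect parameters untouched at their initial values
  expect_equal(fit$estimates$EC50, init$EC50)
  expect_equal(fit$estimates$Kio, init$Kio)
})

test_that("model comparison applies the chi-square decision rule", {
  f1 <- structure(list(objective = 100, free = c("a", "b")),
                  class = "fit_result")
  f2 <- structure(list(objective = 93.36, free = c("a", "b", "c")),
                  class = "fit_result")
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$threshold, qchisq(0.99, 1))
  expect_true(cmp$significant)          # drop 6.64 > 6.63
  expect_false(lrt_significant(0))      # no drop
  expect_false(lrt_significant(6.63))   # exactly at the threshold
  expect_equal(round(qchisq(0.99, 2), 2), 9.21)
  f3 <- structure(list(objective = 90, free = c("a", "d")),
                  class = "fit_result")
  expect_error(compare_models(f3, f2), "nested")
})

test_that("adding the progression term is detected by the likelihood ratio", {
  # data carry the progression signal; the fit with lam free must beat the
  # fit with lam clamped by more than the 6.63 threshold in most replicates
  mouse <- mouse_default_params()
  wins <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    d <- generate_xenograft_study(seed = 300 + r)
    init <- pd_params()
    f_full <- fit_pd(d, mouse, init = init, method = "laplace",
                     compute_rse = FALSE)
    init0 <- pd_params()
    init0$lam <- 1e-6
    f_red <- fit_pd(d, mouse, init = init0, fix = "lam",
                    method = "laplace", compute_rse = FALSE)
    if (compare_models(f_red, f_full, df = 1)$significant) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})
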