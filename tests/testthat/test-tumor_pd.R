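pd <- pd_params()
mouse <- mouse_default_params()

test_that("PD parameter container validates and converts units", {
  expect_equal(pd$Base, 177)
  expect_equal(pd$EC50_KD, 1.02e-5)  # published 0.0102 ug/L, stored in mg/L
  expect_equal(pd$Emax_g, 1)
  expect_error(pd_params(Base = -5), "positive")
})

test_that("the untreated arm follows the closed-form vehicle curve", {
  times <- seq(0, 1632, by = 24)
  sim <- simulate_tumor(pd, mouse, regimen(0, 0), times,
                        rtol = 1e-10, atol = 1e-12)
  cf <- vehicle_tumor_volume(pd, times)
  expect_equal(sim$volume[1], 177)
  expect_equal(sim$volume, cf, tolerance = 1e-6)
  expect_true(all(sim$effect == 1))
  # exponential-progression switch
  pde <- pd_params(progression = "exponential")
  sime <- simulate_tumor(pde, mouse, regimen(0, 0), times,
                         rtol = 1e-10, atol = 1e-12)
  lam_h <- 0.172 / 168
  expect_equal(sime$volume, 177 + 0.338 * (exp(lam_h * times) - 1) / lam_h,
               tolerance = 1e-6)
})

test_that("a saturating constant concentration kills the tumor at KD", {
  # hold the concentration far above both potencies by an enormous slow
  # clearing depot: approximate with a huge bolus and check the terminal
  # log-slope of the volume against the dying rate
  slow <- pk_params(CL = 1e-10, V1 = mouse$V1, Q = 1e-10, V2 = mouse$V2,
                    Vmax = 1e-12, Km = 0.219, body_weight = 0.02)
  times <- seq(0, 2000, 10)
  sim <- simulate_tumor(pd, slow, regimen(0, 5000), times)
  expect_lt(sim$effect[length(times)], 1e-5)  # I -> EC50/C, essentially 0
  # I relaxes at rate Kio towards its (near-zero) asymptote
  expect_equal(sim$effect[times == 10], exp(-0.143 * 10) * 1 +
                 (1 - pd$Emax_g * sim$conc[1] / (pd$EC50 + sim$conc[1])) *
                 (1 - exp(-0.143 * 10)), tolerance = 1e-3)
  lt <- log(sim$volume[times >= 1000])
  slope <- coef(lm(lt ~ times[times >= 1000]))[[2]]
  expect_equal(slope, -0.004, tolerance = 0.02)
})

test_that("the effect state stays within [0, 1] for any regimen", {
  for (amt in c(0.002, 0.05, 0.5)) {
    sim <- simulate_tumor(pd, mouse, weekly_regimen(amt, 4),
                          times = seq(0, 1632, 12))
    expect_true(all(sim$effect >= 0 & sim$effect <= 1 + 1e-8))
    expect_true(all(sim$volume >= 0))
  }
})

test_that("tumor volume at day 21 is non-increasing in dose", {
  doses_kg <- c(0, 1, 2.5, 10, 25)
  v21 <- vapply(doses_kg, function(d) {
    sim <- simulate_tumor(pd, mouse, weekly_regimen(d * 0.02, 3),
                          times = seq(0, 504, 12))
    sim$volume[sim$time == 504]
  }, numeric(1))
  expect_true(all(diff(v21) < 0))
})

test_that("removing the kill term can only let the tumor grow larger", {
  no_kill <- pd_params(EC50_KD = 1e9)
  times <- seq(0, 504, 12)
  treated <- simulate_tumor(pd, mouse, weekly_regimen(0.05, 3), times)
  unkilled <- simulate_tumor(no_kill, mouse, weekly_regimen(0.05, 3), times)
  expect_true(all(unkilled$volume[-1] > treated$volume[-1]))
})

test_that("stasis classification separates vehicle from treated regimens", {
  times <- seq(0, 504, 6)
  veh <- simulate_tumor(pd, mouse, regimen(0, 0), times)
  sv <- stasis_metric(veh, 21)
  expect_equal(sv$classification, "progression")
  expect_equal(stasis_metric(veh, 0)$ratio, 1)
  expect_error(stasis_metric(veh, 30), "cover")
  # the three translated clinical regimens show stasis or regression
  for (mgkg in c(9.5, 20, 24)) {
    tc <- simulate_tumor(pd, mouse, weekly_regimen(mgkg * 0.02, 3), times)
    s <- stasis_metric(tc, 21)
    expect_lte(s$ratio, 1)
    expect_equal(s$classification, "stasis or regression")
  }
})

test_that("AUC-matched translation solves the exposure equation", {
  expect_equal(auc_matched_mouse_dose(0)$weekly_dose_mg, 0)
  # linear-clearance check: with Vmax = 0 in both species the matched dose
  # has the closed form AUC_target * CL_mouse / n
  h_lin <- human_default_params(); h_lin$Vmax <- 0
  m_lin <- scale_params(h_lin, 0.02)
  res <- auc_matched_mouse_dose(360, n_weekly_doses = 3, human = h_lin,
                                mouse = m_lin, human_auc_method = "exact")
  expected <- res$target_auc * 1000 * m_lin$CL / 3
  expect_equal(res$weekly_dose_mg, expected, tolerance = 1e-3)
  # with the full nonlinear model the published translations are
  # reproduced approximately (the matching convention is not published)
  got <- vapply(c(360, 750, 900), function(d) {
    auc_matched_mouse_dose(d)$weekly_dose_mg_per_kg
  }, numeric(1))
  expect_true(all(abs(got / c(9.5, 20, 24) - 1) < 0.15))
})
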