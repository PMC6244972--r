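test_that("parameter containers validate their invariants", {
  expect_error(pk_params(-1, 3.17, 0.03, 3.5, 0.5, 0.2, 70), "positive")
  expect_error(pk_params(0.01, 3.17, 0.03, 3.5, 0.5, Inf, 70), "finite")
  expect_silent(pk_params(0.01, 3.17, 0.03, 3.5, 0, 0.2, 70))  # linear model
  expect_error(allometric_rule(exponent_flow = 2), "exponents")
  expect_error(scale_params(human_default_params(), -1), "positive")
  expect_error(regimen(-1, 10), "non-negative")
  expect_error(regimen(c(0, 168), c(10, -5)), "non-negative")
})

test_that("allometric scaling reproduces the published mouse parameter set", {
  mouse <- mouse_default_params()
  # printed mouse column, at its printed precision
  expect_equal(signif(mouse$CL, 3), 2.75e-5)
  expect_equal(signif(mouse$V1, 3), 9.06e-4)
  expect_equal(signif(mouse$Q, 3), 6.88e-5)
  expect_equal(signif(mouse$V2, 3), 1.00e-3)
  expect_equal(signif(mouse$Vmax, 3), 1.10e-3)
  expect_equal(mouse$Km, 0.219)  # not scaled: cross-reactive target
})

test_that("scaling is an exact power law and round-trips", {
  h <- human_default_params()
  expect_equal(unclass(scale_params(h, 70)), unclass(h))
  m <- scale_params(h, 0.02)
  back <- scale_params(m, 70)
  expect_equal(unclass(back), unclass(h), tolerance = 1e-12)
  # flows with exponent 0.75, volumes with 1
  w <- 3.1
  mk <- scale_params(h, w)
  expect_equal(mk$CL, h$CL * (w / 70)^0.75)
  expect_equal(mk$V2, h$V2 * (w / 70))
  # optional Km scaling switch
  mk2 <- scale_params(h, w, allometric_rule(scale_km = TRUE))
  expect_equal(mk2$Km, h$Km * (w / 70)^0.75)
})

test_that("bolus simulation honors trivial contracts", {
  h <- human_default_params()
  zero <- simulate_pk(h, regimen(0, 0), times = c(0, 10, 100))
  expect_equal(zero$conc, rep(0, 3))
  one <- simulate_pk(h, regimen(0, 360), times = c(0, 1))
  expect_equal(one$conc[1], 360 / 3.17, tolerance = 1e-10)
  expect_equal(one$conc, one$A1 / h$V1)
  expect_error(simulate_pk(h, regimen(0, 10), times = c(5, 1)), "sorted")
})

test_that("with Vmax = 0 the course matches the bi-exponential closed form", {
  set.seed(31)
  times <- c(0.5, 2, 8, 24, 96, 240, 504, 1000)
  for (k in 1:5) {
    p <- pk_params(CL = 10^runif(1, -3, 0), V1 = 10^runif(1, -1, 1),
                   Q = 10^runif(1, -3, 0), V2 = 10^runif(1, -1, 1),
                   Vmax = 0, Km = 0.219, body_weight = 70)
    sim <- simulate_pk(p, regimen(0, 100), times, rtol = 1e-10, atol = 1e-12)
    expect_equal(sim$conc, biexp_conc(p, 100, times), tolerance = 1e-6)
  }
})

test_that("mass is conserved when elimination is shut off", {
  p <- pk_params(CL = 1e-12, V1 = 3.17, Q = 0.0313, V2 = 3.51,
                 Vmax = 0, Km = 0.219, body_weight = 70)
  reg <- regimen(c(0, 100, 250), c(50, 100, 25))
  sim <- simulate_pk(p, reg, times = seq(0, 600, 50),
                     rtol = 1e-10, atol = 1e-12)
  total <- sim$A1 + sim$A2
  dosed <- vapply(sim$time, function(t) sum(reg$amount[reg$time <= t]),
                  numeric(1))
  expect_equal(total, dosed, tolerance = 1e-7)
})

test_that("superposition holds for the linear model and fails near Km", {
  h <- human_default_params()
  lin <- h; lin$Vmax <- 0
  times <- seq(0, 800, 25)
  reg2 <- regimen(c(0, 336), c(100, 100))
  multi <- simulate_pk(lin, reg2, times, rtol = 1e-10, atol = 1e-12)$conc
  s1 <- simulate_pk(lin, regimen(0, 100), times,
                    rtol = 1e-10, atol = 1e-12)$conc
  shifted <- c(rep(0, sum(times < 336)),
               simulate_pk(lin, regimen(0, 100), times[times >= 336] - 336,
                           rtol = 1e-10, atol = 1e-12)$conc)
  expect_equal(multi, s1 + shifted, tolerance = 1e-6)
  # saturable clearance: a second low dose given while the first is still
  # crossing the Km transition does not superpose
  tt <- seq(0, 72, 1)
  low <- regimen(c(0, 4), c(1, 1))
  multi_nl <- simulate_pk(h, low, tt, rtol = 1e-10, atol = 1e-12)$conc
  s1_nl <- simulate_pk(h, regimen(0, 1), tt,
                       rtol = 1e-10, atol = 1e-12)$conc
  shifted_nl <- rep(0, length(tt))
  shifted_nl[tt >= 4] <- simulate_pk(h, regimen(0, 1), tt[tt >= 4] - 4,
                                     rtol = 1e-10, atol = 1e-12)$conc
  expect_gt(max(abs(multi_nl - (s1_nl + shifted_nl)) /
                  pmax(multi_nl, 0.01)), 0.05)
})

test_that("saturable clearance makes AUC/dose non-decreasing in dose", {
  h <- human_default_params()
  doses <- c(1, 5, 20, 100, 500, 2000)
  ratio <- auc_inf(h, doses, method = "exact") * 1000 / doses
  expect_true(all(diff(ratio) > 0))
})

test_that("regimens round-trip through CSV", {
  reg <- weekly_regimen(0.05, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_regimen(reg, path)
  back <- read_regimen(path, cycle_length = attr(reg, "cycle_length"))
  expect_equal(back$time, reg$time)
  expect_equal(back$amount, reg$amount)
  expect_equal(back$route, reg$route)
})
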