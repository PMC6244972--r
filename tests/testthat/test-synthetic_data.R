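test_that("the caliper formula is width-squared times length over two", {
  expect_equal(caliper_volume(10, 10), 500)
  expect_equal(caliper_volume(2, 4), 8)
  expect_equal(caliper_volume(3, 8), 2 * caliper_volume(3, 4))
  expect_error(caliper_volume(0, 4), "positive")
  expect_error(caliper_volume(5, 4), "width")
})

test_that("the monkey study designs have the reported shape", {
  d <- generate_monkey_pk_study(seed = 1, lloq = NULL)
  expect_equal(length(unique(d$ID)), 6)              # 3 dose groups x 2
  expect_equal(sum(d$EVID == 0), 6 * 14)             # 14 samples per animal
  expect_equal(sort(unique(d$DOSEGRP)), c(10, 30, 100))
  expect_true(all(d$WT >= 2.5 & d$WT <= 3.5))
  # weight-based dosing
  doses <- d[d$EVID == 1, ]
  expect_equal(doses$AMT, doses$DOSEGRP * doses$WT)
  r <- generate_monkey_pk_study(design = monkey_repeat_dose_design(),
                                seed = 2, lloq = NULL)
  expect_equal(length(unique(r$ID)), 22)             # 6 + 6 + 10 animals
  expect_equal(sum(r$EVID == 0), 22 * 10)            # 10 samples per animal
  expect_lte(max(r$TIME), 168)
})

test_that("zero variability reproduces the noise-free predictions", {
  tiny <- residual_spec(1e-12, 0)
  d <- generate_monkey_pk_study(omega = omega_spec(), residual = tiny,
                                lloq = NULL, seed = 3)
  h <- human_default_params()
  for (id in unique(d$ID)) {
    s <- d[d$ID == id, ]
    obs <- s[s$EVID == 0, ]
    f <- simulate_pk(scale_params(h, obs$WT[1]),
                     regimen(0, s$AMT[s$EVID == 1]), obs$TIME)$conc
    expect_equal(obs$DV, f, tolerance = 1e-6)
  }
})

test_that("generated datasets are reproducible and round-trip losslessly", {
  a <- generate_monkey_pk_study(seed = 42)
  b <- generate_monkey_pk_study(seed = 42)
  attr(a, "manifest") <- attr(b, "manifest") <- NULL
  expect_identical(a, b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(a, path)
  back <- read_dataset(path)
  expect_equal(back, validate_dataset(a), tolerance = 1e-12)
})

test_that("the BLQ rule shapes the low tail of generated data", {
  d <- generate_monkey_pk_study(seed = 8)
  blq <- d[d$BLQ == 1, ]
  expect_true(all(blq$DV == 0.039))
  # at most one retained below-limit record per animal
  expect_true(all(table(blq$ID) <= 1))
})

test_that("the xenograft study reproduces the design and its dropout", {
  d <- generate_xenograft_study(seed = 9)
  expect_equal(length(unique(d$ID)), 30)
  expect_equal(sort(unique(d$DOSEGRP)), c(0, 2.5, 25))
  obs <- d[d$EVID == 0, ]
  # twice-weekly grid (days 0, 3, 7, 10, ... relative to treatment start)
  days <- sort(unique(obs$TIME)) / 24
  expect_true(all(days %in% sort(c(seq(0, 68, 7), seq(3, 68, 7)))))
  expect_lte(max(obs$TIME), 68 * 24)
  # baselines inside the admissible window (up to measurement noise)
  base0 <- obs$DV[obs$TIME == 0]
  expect_true(all(base0 > 108 * 0.4 & base0 < 172 * 2.5))
  # censoring: records stop after the first observation at or above
  # 800 mm^3
  for (id in unique(obs$ID)) {
    v <- obs$DV[obs$ID == id]
    over <- which(v >= 800)
    if (length(over)) expect_equal(over[1], length(v))
  }
})

test_that("vehicle mice mostly hit the euthanasia threshold early", {
  d <- generate_xenograft_study(seed = 10)
  obs <- d[d$EVID == 0, ]
  last_day <- tapply(obs$TIME, obs$ID, max) / 24
  arm <- tapply(obs$DOSEGRP, obs$ID, unique)
  expect_gt(mean(last_day[arm == 0] < 68), 0.5)
  # higher dose arms are censored later
  expect_lt(median(last_day[arm == 0]), median(last_day[arm == 25]))
  expect_lte(median(last_day[arm == 2.5]), median(last_day[arm == 25]))
})

test_that("noise-free vehicle trajectories equal the closed form", {
  d <- generate_xenograft_study(residual = residual_spec(1e-12, 0),
                                seed = 11)
  obs <- d[d$EVID == 0 & d$DOSEGRP == 0, ]
  man <- attr(d, "manifest")
  for (id in unique(obs$ID)) {
    s <- obs[obs$ID == id, ]
    pd_i <- pd_params()
    eta <- man$eta[[id]]
    pd_i$Base <- pd_i$Base * exp(eta[["Base"]])
    pd_i$KG <- pd_i$KG * exp(eta[["KG"]])
    expect_equal(s$DV, vehicle_tumor_volume(pd_i, s$TIME), tolerance = 1e-6)
  }
})

test_that("simulated between-subject spread matches the configured CV", {
  h <- human_default_params()
  set.seed(77)
  cl <- replicate(1e4, draw_individual(h, omega_spec(CL = 13.2))$CL)
  expect_lt(abs(100 * sd(cl) / mean(cl) - 13.2), 1)
})
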