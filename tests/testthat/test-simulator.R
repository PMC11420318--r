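test_that("input contracts are enforced", {
  p <- lf_params(v = 1, a = 1, alpha = 1.5)
  expect_error(simulate_trials(p, 10, dt = 0.05), "dt")
  expect_error(simulate_trials(p, 10, t_max = 0.1), "t_max")
  expect_error(lf_params(v = 1, a = -1), "'a'")
  expect_error(lf_params(v = 1, a = 1, zr = 1.2), "zr")
  expect_error(lf_params(v = 1, a = 1, alpha = 0.8), "alpha")
  expect_error(lf_params(v = 1, a = 1, zr = 0.1, szr = 0.4), "szr")
  expect_error(lf_params(v = 1, a = 1, t0 = 0.1, st = 0.5), "st")
})

test_that("symmetric process is unbiased and rts respect non-decision time", {
  set.seed(21)
  sim <- simulate_trials(lf_params(v = 0, a = 1, t0 = 0.25, alpha = 1.5),
                         2e4, dt = 1e-3)
  expect_lt(abs(mean(sim$choice == "upper") - 0.5),
            3 * sqrt(0.25 / nrow(sim)))
  expect_gte(min(sim$rt), 0.25)
  expect_true(all(sim$rt > sim$decision_time))
})

test_that("Gaussian limit reproduces the Wiener absorption probability", {
  set.seed(22)
  sim <- simulate_trials(lf_params(v = 1, a = 1, t0 = 0.3, alpha = 2),
                         3e4, dt = 1e-4)
  p_up <- oracle_wiener_p_upper(1, 1, 0.5)   # 0.7311
  expect_lt(abs(mean(sim$choice == "upper") - p_up),
            3 * sqrt(p_up * (1 - p_up) / nrow(sim)))
})

test_that("datasets have the configured epoch structure and reproduce", {
  pars <- lapply(c(2, 1.5, 1.2, 1), function(a)
    lf_params(v = 1.2, a = a, t0 = 0.4, alpha = 1.5))
  set.seed(23)
  d1 <- simulate_dataset(pars, n_per_epoch = 240)
  expect_s3_class(d1, "lf_data")
  expect_equal(nrow(d1), 960)
  expect_equal(as.numeric(table(d1$epoch)), rep(240, 4))
  set.seed(23)
  d2 <- simulate_dataset(pars, n_per_epoch = 240)
  expect_identical(d1, d2)
})

test_that("decreasing thresholds speed responses across epochs", {
  # epoch thresholds follow the high-information practice trajectory
  set.seed(24)
  pars <- lapply(c(4.51, 1.79, 1.91, 1.43), function(a)
    lf_params(v = 1.3, a = a, zr = 0.5, t0 = 0.46, alpha = 1.4))
  d <- simulate_dataset(pars, n_per_epoch = 5000)
  mrt <- tapply(d$rt, d$epoch, mean)
  expect_gt(mrt[[1]], mrt[[2]])
  expect_gt(mrt[[2]], mrt[[4]])
  expect_gt(mrt[[1]], mrt[[4]])
})

test_that("lower alpha produces more large jumps", {
  set.seed(25)
  thr <- 5 / sqrt(2)   # 5 gamma, on the standard scale
  frac <- vapply(c(1.2, 1.5, 1.8, 2), function(al) {
    mean(abs(rstable(2e5, stable_params(al))) > thr)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("choice, censoring and totals partition every simulated set", {
  set.seed(26)
  sim <- simulate_trials(lf_params(v = 0.2, a = 6, t0 = 0.3, alpha = 2),
                         500, dt = 5e-3, t_max = 3, censored = "flag")
  n_up <- sum(sim$choice == "upper", na.rm = TRUE)
  n_lo <- sum(sim$choice == "lower", na.rm = TRUE)
  n_cen <- sum(is.na(sim$choice))
  expect_gt(n_cen, 0)                     # cutoff chosen to censor some
  expect_identical(n_up + n_lo + n_cen, nrow(sim))
  expect_true(all(is.na(sim$rt[is.na(sim$choice)])))
})

test_that("halving the step leaves the choice fraction stable", {
  p <- lf_params(v = 1, a = 1, t0 = 0.3, alpha = 1.5)
  set.seed(27)
  f1 <- mean(simulate_trials(p, 1e5, dt = 1e-3)$choice == "upper")
  f2 <- mean(simulate_trials(p, 1e5, dt = 5e-4)$choice == "upper")
  expect_lt(abs(f1 - f2), 2 * sqrt(f1 * (1 - f1) / 1e5))
})
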