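test_that("solver rejects unsupported configurations", {
  expect_error(fpde_solve(lf_params(v = 1, a = 1, alpha = 1)), "alpha")
  expect_error(fpde_solve(lf_params(v = 1, a = 1, alpha = 1.5), nx = 20),
               "nx")
})

test_that("initial mass, boundaries and monotone survival hold", {
  g <- fpde_solve(lf_params(v = 1, a = 1, zr = 0.5, alpha = 1.5),
                  nx = 100, nt = 200, T = 2)
  S <- survival(g)
  expect_equal(S[1], 1, tolerance = 1e-6)
  expect_true(all(g$p[1, ] == 0))
  expect_true(all(g$p[nrow(g$p), ] == 0))
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(g$p >= -1e-12))
})

test_that("Gaussian limit matches the analytic Wiener survival", {
  g <- fpde_solve(lf_params(v = 1, a = 1, zr = 0.5, alpha = 2),
                  nx = 200, nt = 800, T = 3)
  expect_lt(max(abs(survival(g) - wiener_survival(g$t, 1, 1, 0.5))), 0.01)
  # and the exit split integrates to the closed-form absorption probability
  dt <- diff(g$t)[1]
  expect_equal(sum(g$g_upper[-1]) * dt, oracle_wiener_p_upper(1, 1, 0.5),
               tolerance = 0.01)
  # the pointwise exit-density check needs a fine grid: the density peaks
  # sharply (~2.5/s near t = 0.05) and the stepping is first order in time
  g2 <- fpde_solve(lf_params(v = 1, a = 1, zr = 0.5, alpha = 2),
                   nx = 400, nt = 12800, T = 3)
  expect_lt(max(abs(g2$g_upper -
                      wiener_fpt_density(g2$t, 1, 1, 0.5, "upper"))), 0.02)
})

test_that("fractional survival agrees with Monte-Carlo simulation", {
  set.seed(31)
  p <- lf_params(v = 1, a = 1, zr = 0.5, t0 = 0, alpha = 1.5)
  g <- fpde_solve(p, nx = 150, nt = 500, T = 3)
  sim <- simulate_trials(p, 4e4, dt = 5e-4, censored = "flag")
  expect_lt(max(abs(survival(g) - mc_survival(sim, g$t))), 0.02)
})

test_that("mass is conserved and exits balance survival", {
  for (al in c(1.3, 1.7, 2)) {
    g <- fpde_solve(lf_params(v = 0.8, a = 1.2, zr = 0.4, alpha = al),
                    nx = 120, nt = 300, T = 3)
    dt <- diff(g$t)[1]
    total <- survival(g)[length(g$t)] +
      sum(g$g_upper[-1] + g$g_lower[-1]) * dt
    expect_lt(abs(total - 1), 0.02)
    expect_true(all(g$g_upper >= 0) && all(g$g_lower >= 0))
  }
})

test_that("symmetric problems give identical exit densities", {
  g <- fpde_solve(lf_params(v = 0, a = 1, zr = 0.5, alpha = 1.5),
                  nx = 100, nt = 200, T = 2)
  expect_lt(max(abs(g$g_upper - g$g_lower)), 1e-3)
})

test_that("strong drift drives survival to zero", {
  g <- fpde_solve(lf_params(v = 8, a = 1, zr = 0.5, alpha = 1.5),
                  nx = 100, nt = 200, T = 2)
  expect_lt(survival(g)[length(g$t)], 1e-4)
})

test_that("solutions converge in the grid and are continuous at alpha = 2", {
  p <- lf_params(v = 1, a = 1, zr = 0.5, alpha = 1.6)
  S1 <- survival(fpde_solve(p, nx = 100, nt = 200, T = 2))
  S2 <- survival(fpde_solve(p, nx = 200, nt = 400, T = 2))
  expect_lt(abs(S1[length(S1)] - S2[length(S2)]), 0.005)
  p99 <- lf_params(v = 1, a = 1, zr = 0.5, alpha = 1.99)
  p2 <- lf_params(v = 1, a = 1, zr = 0.5, alpha = 2)
  SA <- survival(fpde_solve(p99, nx = 100, nt = 300, T = 2))
  SB <- survival(fpde_solve(p2, nx = 100, nt = 300, T = 2))
  expect_lt(abs(SA[length(SA)] - SB[length(SB)]), 0.02)
})

test_that("quadrature mixing over drift variability changes the density", {
  p0 <- lf_params(v = 1, a = 1.5, zr = 0.5, alpha = 1.8)
  pv <- lf_params(v = 1, a = 1.5, zr = 0.5, alpha = 1.8, sv = 1)
  f0 <- fpde_fpt(p0, nx = 100, nt = 200, T = 2.5)
  fv <- fpde_fpt(pv, nx = 100, nt = 200, T = 2.5)
  # mixture mass still balances
  dt <- diff(f0$t)[1]
  tot <- fv$S[length(fv$t)] + sum(fv$g_upper[-1] + fv$g_lower[-1]) * dt
  expect_lt(abs(tot - 1), 0.02)
  # drift variability thickens the lower (error) exit
  expect_gt(sum(fv$g_lower), sum(f0$g_lower))
})
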