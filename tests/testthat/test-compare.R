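test_that("information criteria follow both conventions", {
  # worked example from the published fit table, model-1 column
  ic <- information_criteria(-61624, 330, 960)
  expect_equal(unname(ic["AIC"]), 123578)
  expect_equal(unname(ic["BIC"]), 123248 + 330 * log(960))
  # textbook convention
  ic2 <- information_criteria(-100, 5, 50, convention = "standard",
                              n_total = 200)
  expect_equal(unname(ic2["AIC"]), 210)
  expect_equal(unname(ic2["BIC"]), 200 + 5 * log(200))
  # no parameters: both reduce to -2 logL
  ic0 <- information_criteria(-123.4, 0, 960)
  expect_equal(unname(ic0), c(246.8, 246.8))
})

test_that("paper-convention identities hold for any inputs", {
  set.seed(51)
  for (i in 1:20) {
    logL <- -runif(1, 1e3, 1e5)
    k <- sample(10:500, 1)
    n <- sample(100:2000, 1)
    ic <- information_criteria(logL, k, n)
    expect_equal(ic[["AIC"]] - (-2 * logL), k)
    expect_equal(ic[["BIC"]] - ic[["AIC"]], k * (log(n) - 1))
  }
})

test_that("epoch change summary averages per-participant percent changes", {
  m <- lf_model("alpha_varying")
  mk <- function(a1, a4) {
    th <- c(v = 1, zr = 0.5, t0 = 0.3, a1 = 2, a2 = 2, a3 = 2, a4 = 2,
            alpha1 = a1, alpha2 = a1, alpha3 = a4, alpha4 = a4)
    levydm:::new_lf_fit("p", m, th)
  }
  expect_equal(epoch_change_summary(list(mk(1.4, 1.4)), "alpha"), 0)
  expect_equal(epoch_change_summary(list(mk(1.0, 1.1), mk(1.0, 1.2)),
                                    "alpha"), 15)
  expect_equal(epoch_change_summary(list(mk(1.00, 1.17), mk(1.20, 1.404)),
                                    "alpha"), 17, tolerance = 1e-6)
  expect_error(epoch_change_summary(list(mk(1, 1)), "v"), "epoch-indexed")
  expect_error(epoch_change_summary(list(mk(1, 1)), "sv"), "epoch-indexed")
})

test_that("predictive checks use type-7 quantiles and flag sparse sides", {
  expect_equal(quantile(1:10, 0.5, type = 7, names = FALSE), 5.5)
  set.seed(52)
  m <- lf_model("alpha_varying")
  th <- c(v = 1.5, zr = 0.5, t0 = 0.3, a1 = 1.5, a2 = 1.5, a3 = 1.5,
          a4 = 1.5, alpha1 = 1.6, alpha2 = 1.6, alpha3 = 1.6, alpha4 = 1.6)
  fit <- levydm:::new_lf_fit("p1", m, th)
  d <- simulate(fit, nsim = 60)
  pc <- predictive_check(d, fit, n_sim = 2000)
  expect_setequal(unique(pc$source), c("observed", "predicted"))
  expect_equal(nrow(pc), 4 * 2 * 2)      # epoch x side x source
  # an all-upper epoch has observed accuracy 1 and no lower quantiles
  d2 <- d
  d2$choice[d2$epoch == 1] <- "upper"
  pc2 <- predictive_check(as_lf_data(d2), fit, n_sim = 500)
  obs1 <- pc2[pc2$epoch == 1 & pc2$source == "observed", ]
  expect_equal(unique(obs1$accuracy), 1)
  expect_true(all(is.na(obs1[obs1$side == "lower",
                             c("q10", "q30", "q50", "q70", "q90")])))
})

test_that("a fit reproduces its own data in the predictive check", {
  set.seed(53)
  m <- lf_model("alpha_varying")
  th <- c(v = 1.3, zr = 0.5, t0 = 0.4, a1 = 1.8, a2 = 1.8, a3 = 1.8,
          a4 = 1.8, alpha1 = 1.5, alpha2 = 1.5, alpha3 = 1.5, alpha4 = 1.5)
  fit <- levydm:::new_lf_fit("p1", m, th)
  diffs <- replicate(10, {
    d <- simulate(fit, nsim = 120)
    pc <- predictive_check(d, fit, n_sim = 3000)
    up <- pc[pc$side == "upper", ]
    mean(up$q50[up$source == "observed"] - up$q50[up$source == "predicted"],
         na.rm = TRUE)
  })
  # paired median differences center on zero across replicates
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.01)
})
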