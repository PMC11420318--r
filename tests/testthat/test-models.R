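test_that("the model registry matches the published parameter counts", {
  ks <- vapply(lf_model_names(), function(n) lf_model(n)$k, numeric(1))
  expect_equal(unname(ks), c(11, 12, 12, 12, 14))
  m <- lf_model("alpha_varying")
  expect_setequal(m$per_epoch, c("a", "alpha"))
  expect_setequal(lf_model("drift_alpha_varying")$per_epoch,
                  c("a", "v", "alpha"))
  expect_setequal(lf_model("drift_variability")$per_epoch, c("a", "sv"))
  expect_setequal(lf_model("startpoint_variability")$per_epoch, c("a", "szr"))
  expect_setequal(lf_model("ndt_variability")$per_epoch, c("a", "st"))
  expect_error(lf_model("nonexistent"))
})

test_that("prior draws respect ranges and joint constraints", {
  set.seed(41)
  for (mn in c("alpha_varying", "startpoint_variability", "ndt_variability")) {
    m <- lf_model(mn)
    th <- sample_prior(m, 500)
    expect_equal(dim(th), c(500, m$k))
    pr <- default_priors()
    for (nm in colnames(th)) {
      r <- pr[[levydm:::par_base(nm)]]
      expect_true(all(th[, nm] >= r[1] & th[, nm] <= r[2]))
    }
    # every draw yields valid per-epoch parameter objects
    for (i in 1:20) {
      expect_silent(levydm:::theta_to_params(m, th[i, ]))
    }
  }
})

test_that("theta expansion routes shared and epoch-wise values correctly", {
  m <- lf_model("alpha_varying")
  th <- c(v = 1.2, zr = 0.45, t0 = 0.3, a1 = 2, a2 = 1.8, a3 = 1.5,
          a4 = 1.2, alpha1 = 1.3, alpha2 = 1.4, alpha3 = 1.5, alpha4 = 1.6)
  pars <- levydm:::theta_to_params(m, th)
  expect_length(pars, 4)
  expect_equal(vapply(pars, `[[`, 1, "a"), c(2, 1.8, 1.5, 1.2))
  expect_equal(vapply(pars, `[[`, 1, "alpha"), c(1.3, 1.4, 1.5, 1.6))
  expect_true(all(vapply(pars, `[[`, 1, "v") == 1.2))
  expect_true(all(vapply(pars, `[[`, 1, "sv") == 0))
})

test_that("encoding has one sorted signed channel per epoch", {
  set.seed(42)
  pars <- lapply(c(2, 1.5, 1.2, 1), function(a)
    lf_params(v = 1, a = a, t0 = 0.3, alpha = 1.5))
  d <- simulate_dataset(pars, n_per_epoch = 30)
  enc <- encode_dataset(d)
  expect_equal(dim(enc), c(4, 30))
  expect_true(all(apply(enc, 1, function(r) all(diff(r) >= 0))))
  expect_equal(sort(abs(enc[1, ])), sort(d$rt[d$epoch == 1]),
               tolerance = 1e-12)
  # signs recode the choices: negative entries are lower-boundary responses
  expect_equal(sum(enc[1, ] < 0), sum(d$choice[d$epoch == 1] == "lower"))
  # permuting trials within an epoch leaves the encoding unchanged
  d2 <- d[sample(nrow(d)), ]
  expect_equal(encode_dataset(as_lf_data(d2)), enc)
  # an all-upper epoch encodes all-positive
  d3 <- d
  d3$choice[d3$epoch == 2] <- "upper"
  expect_true(all(encode_dataset(as_lf_data(d3))[2, ] > 0))
  # ragged epochs are rejected
  expect_error(encode_dataset(as_lf_data(d[-1, ])), "same number")
})
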