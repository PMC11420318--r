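small_cfg <- function(...) {
  study_config(trials_per_epoch = 60, ...)
}

test_that("study generation has the configured shape and ground truth", {
  set.seed(81)
  st <- generate_study(study_config(participants = c(high = 1),
                                    trials_per_epoch = 240))
  expect_equal(nrow(st$data), 960)
  expect_equal(sort(unique(st$data$epoch)), 1:4)
  gt <- st$ground_truth
  expect_setequal(unique(gt$parameter), c("a", "v", "zr", "t0", "alpha"))
  expect_equal(sum(gt$parameter == "a"), 4)
})

test_that("high-information ground truth has rising alpha and falling threshold", {
  set.seed(82)
  st <- generate_study(small_cfg(participants = c(high = 12)))
  gt <- st$ground_truth
  a1 <- gt$value[gt$parameter == "alpha" & gt$epoch == 1 & !is.na(gt$epoch)]
  a4 <- gt$value[gt$parameter == "alpha" & gt$epoch == 4 & !is.na(gt$epoch)]
  # condition-level practice effect: epoch-4 alpha above epoch-1 on average
  expect_gt(mean(a4 - a1), 0)
  th1 <- gt$value[gt$parameter == "a" & gt$epoch == 1 & !is.na(gt$epoch)]
  th4 <- gt$value[gt$parameter == "a" & gt$epoch == 4 & !is.na(gt$epoch)]
  expect_gt(mean(th1 - th4), 0)
  # all ground truth lies inside the training-prior support
  pr <- default_priors()
  expect_true(all(a1 >= pr$alpha[1] & a1 <= pr$alpha[2]))
  expect_true(all(th1 >= pr$a[1] & th1 <= pr$a[2]))
})

test_that("generation is reproducible to the byte through the CSV dialect", {
  set.seed(83)
  st1 <- generate_study(small_cfg(participants = c(medium = 2)))
  set.seed(83)
  st2 <- generate_study(small_cfg(participants = c(medium = 2)))
  f1 <- tempfile(); f2 <- tempfile()
  write_trials(st1$data, f1); write_trials(st2$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(st1$ground_truth, st2$ground_truth)
})

test_that("generated accuracy sits in the studied regime", {
  set.seed(84)
  st <- generate_study(small_cfg())
  acc <- tapply(st$data$choice == "upper", st$data$participant, mean)
  expect_gte(mean(acc >= 0.7 & acc <= 0.98), 0.9)
})

test_that("practice speeds responses in the high-information condition", {
  set.seed(85)
  st <- generate_study(small_cfg(participants = c(high = 8)))
  d <- st$data
  m1 <- mean(d$rt[d$epoch == 1])
  m4 <- mean(d$rt[d$epoch == 4])
  expect_gt(m1, m4)
})

test_that("exclusion keeps the boundary case and reports accuracies", {
  d <- data.frame(participant = rep(c("p1", "p2", "p3"), each = 20),
                  condition = "high", epoch = 1, trial = 1:20,
                  choice = c(rep("upper", 13), rep("lower", 7),    # 0.65
                             rep("upper", 14), rep("lower", 6),    # 0.70
                             rep("upper", 20)),                    # 1.00
                  rt = 0.5, stringsAsFactors = FALSE)
  ex <- apply_exclusion(as_lf_data(d), threshold = 0.70)
  expect_setequal(unique(ex$data$participant), c("p2", "p3"))
  expect_equal(ex$report$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(ex$report$accuracy, c(0.65, 0.70, 1.00))
  # threshold zero retains everyone
  ex0 <- apply_exclusion(as_lf_data(d), threshold = 0)
  expect_equal(nrow(ex0$report[ex0$report$excluded, ]), 0)
})
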