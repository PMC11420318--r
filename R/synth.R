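#' Condition-level ground-truth parameter trajectories
#'
#' Default epoch-indexed parameter trajectories for the three feedback
#' conditions of the fixed-trial practice design, centered on the published
#' condition means for the epoch-varying model: decision thresholds
#' decrease with practice while the stability index alpha increases, most
#' strongly under high-information feedback and flattest under low.
#' Between-participant SDs are the square roots of the published
#' across-participant variances.
#'
#' @return Named list (`high`, `medium`, `low`); each entry has `mean` and
#'   `sd` sub-lists with `a` and `alpha` vectors over 4 epochs and scalars
#'   `v`, `zr`, `t0`.
#' @export
default_trajectories <- function() {
  list(
    high = list(
      mean = list(a = c(4.51, 1.79, 1.91, 1.43), v = 1.30, zr = 0.50,
                  t0 = 0.46, alpha = c(1.33, 1.39, 1.47, 1.50)),
      sd = list(a = sqrt(c(6.72, 0.09, 0.26, 0.15)), v = sqrt(0.37),
                zr = sqrt(0.01), t0 = sqrt(0.01),
                alpha = sqrt(c(0.05, 0.03, 0.02, 0.01)))),
    medium = list(
      mean = list(a = c(3.00, 2.09, 1.91, 1.62), v = 1.71, zr = 0.52,
                  t0 = 0.47, alpha = c(1.29, 1.46, 1.46, 1.48)),
      sd = list(a = sqrt(c(2.56, 0.59, 0.45, 0.20)), v = sqrt(0.35),
                zr = sqrt(0.02), t0 = sqrt(0.006),
                alpha = sqrt(c(0.02, 0.02, 0.04, 0.05)))),
    low = list(
      mean = list(a = c(2.81, 2.46, 2.10, 1.78), v = 1.12, zr = 0.51,
                  t0 = 0.49, alpha = c(1.42, 1.49, 1.55, 1.44)),
      sd = list(a = sqrt(c(2.69, 0.56, 0.42, 0.49)), v = sqrt(0.18),
                zr = sqrt(0.01), t0 = sqrt(0.004),
                alpha = sqrt(c(0.02, 0.04, 0.006, 0.01)))))
}

#' Study-shaped synthetic-data configuration
#'
#' Emulates the fixed-trial practice design: three feedback conditions
#' (10 low / 9 medium / 11 high participants after exclusions), four trial
#' epochs of 240 trials, individual-level parameters drawn around the
#' condition trajectories, and an accuracy-based exclusion rule.
#'
#' @param participants Named counts per condition.
#' @param n_epochs Trial epochs per participant.
#' @param trials_per_epoch Trials per epoch.
#' @param trajectories Ground-truth trajectories, as
#'   [default_trajectories()].
#' @param exclusion_threshold Minimum overall accuracy retained.
#' @param dt Euler step for the simulations.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(participants = c(low = 10, medium = 9, high = 11),
                         n_epochs = 4L, trials_per_epoch = 240,
                         trajectories = default_trajectories(),
                         exclusion_threshold = 0.70, dt = 0.001) {
  stopifnot(all(participants >= 1), !is.null(names(participants)))
  structure(list(participants = participants,
                 n_epochs = as.integer(n_epochs),
                 trials_per_epoch = as.integer(trials_per_epoch),
                 trajectories = trajectories,
                 exclusion_threshold = exclusion_threshold, dt = dt),
            class = "study_config")
}

# individual-level draw around a condition trajectory, truncated to the
# training-prior support so that ground truth stays recoverable
draw_participant_theta <- function(traj, n_epochs,
                                   priors = default_priors()) {
  rtrunc <- function(mean, sd, lo, hi) {
    for (i in 1:100) {
      x <- rnorm(length(mean), mean, sd)
      if (all(x >= lo & x <= hi)) return(x)
    }
    pmin(pmax(x, lo), hi)
  }
  list(a = rtrunc(traj$mean$a[seq_len(n_epochs)],
                  traj$sd$a[seq_len(n_epochs)],
                  priors$a[1], priors$a[2]),
       v = rtrunc(traj$mean$v, traj$sd$v, priors$v[1], priors$v[2]),
       zr = rtrunc(traj$mean$zr, traj$sd$zr, priors$zr[1], priors$zr[2]),
       t0 = rtrunc(traj$mean$t0, traj$sd$t0, priors$t0[1], priors$t0[2]),
       alpha = rtrunc(traj$mean$alpha[seq_len(n_epochs)],
                      traj$sd$alpha[seq_len(n_epochs)],
                      priors$alpha[1], priors$alpha[2]))
}

#' Generate a synthetic study with known ground truth
#'
#' Draws individual-level parameters for every participant (Normal around
#' the condition trajectory, truncated to the training-prior support),
#' simulates all epochs, and returns both the trial data and the exact
#' ground truth used, for recovery scoring.  The upper boundary is the
#' correct response throughout (positive drift), so accuracy is the upper
#' fraction.
#'
#' @param cfg A [study_config()].
#' @return List with `data` (one `lf_data` covering all participants),
#'   `ground_truth` (long data frame: participant, condition, parameter,
#'   epoch, value), and `config`.
#' @examples
#' set.seed(42)
#' cfg <- study_config(participants = c(high = 2), trials_per_epoch = 24)
#' st <- generate_study(cfg)
#' nrow(st$data)  # 2 * 4 * 24
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  all_data <- list(); gt <- list()
  pid <- 0L
  for (cond in names(cfg$participants)) {
    traj <- cfg$trajectories[[cond]]
    if (is.null(traj)) stop("no trajectory for condition ", cond, call. = FALSE)
    for (i in seq_len(cfg$participants[[cond]])) {
      pid <- pid + 1L
      id <- sprintf("%s%02d", substr(cond, 1, 1), i)
      th <- draw_participant_theta(traj, cfg$n_epochs)
      pars <- lapply(seq_len(cfg$n_epochs), function(e) {
        lf_params(v = th$v, a = th$a[e], zr = th$zr, t0 = th$t0,
                  alpha = th$alpha[e])
      })
      all_data[[pid]] <- simulate_dataset(pars, cfg$trials_per_epoch,
                                          participant = id,
                                          condition = cond, dt = cfg$dt)
      gt[[pid]] <- data.frame(
        participant = id, condition = cond,
        parameter = c(rep("a", cfg$n_epochs), "v", "zr", "t0",
                      rep("alpha", cfg$n_epochs)),
        epoch = c(seq_len(cfg$n_epochs), NA, NA, NA, seq_len(cfg$n_epochs)),
        value = c(th$a, th$v, th$zr, th$t0, th$alpha),
        stringsAsFactors = FALSE)
    }
  }
  list(data = as_lf_data(do.call(rbind, all_data)),
       ground_truth = do.call(rbind, gt), config = cfg)
}

#' Exclude participants below an accuracy threshold
#'
#' Retains participants whose overall accuracy (fraction of upper-boundary,
#' i.e. correct, responses) is at least `threshold`; the boundary case is
#' retained.
#'
#' @param data An `lf_data` covering one or more participants.
#' @param threshold Accuracy threshold (default 0.70).
#' @return List with `data` (retained trials) and `report` (data frame:
#'   participant, accuracy, excluded).
#' @export
apply_exclusion <- function(data, threshold = 0.70) {
  acc <- tapply(data$choice == "upper", data$participant, mean)
  report <- data.frame(participant = names(acc),
                       accuracy = as.numeric(acc),
                       excluded = as.numeric(acc) < threshold,
                       stringsAsFactors = FALSE)
  keep <- report$participant[!report$excluded]
  list(data = as_lf_data(data[data$participant %in% keep, , drop = FALSE]),
       report = report)
}
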