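#' Simulate trials from the Levy-flight process
#'
#' Forward Euler simulation of the accumulation rule
#' \eqn{X(t+\Delta t) = X(t) + v\,\Delta t + e\,\Delta t^{1/\alpha}} with
#' \eqn{e \sim \mathrm{Stable}(\alpha, 0, 1/\sqrt{2}, 0)}, absorbed at the
#' first step whose end state reaches either boundary (no crossing-time
#' interpolation: with heavy-tailed jumps the path has no continuity to
#' interpolate).  Per-trial drift, start point and non-decision time are
#' drawn fresh each trial from the between-trial distributions.
#'
#' Trials still unabsorbed at `t_max` are either resampled (up to
#' `max_attempts` fresh attempts, the generator default) or flagged with
#' `NA` choice and response time (`censored = "flag"`, appropriate whenever
#' densities must not be biased by resampling).
#'
#' @param params An [lf_params()] object.
#' @param n Number of trials.
#' @param dt Euler step (s), in (0, 0.01].
#' @param t_max Decision-time cutoff (s); must exceed `t0`.
#' @param censored Policy for non-absorbed trials: `"resample"` or `"flag"`.
#' @param max_attempts Resampling attempts per trial under `"resample"`.
#' @return A data frame with columns `choice` (`"upper"`/`"lower"`, `NA` if
#'   censored), `rt` (s, decision + non-decision time) and `decision_time`.
#' @examples
#' set.seed(1)
#' head(simulate_trials(lf_params(v = 1, a = 1, alpha = 1.5), 5))
#' @export
simulate_trials <- function(params, n, dt = 0.001, t_max = 10,
                            censored = c("resample", "flag"),
                            max_attempts = 100L) {
  params <- as_lf_params(params)
  censored <- match.arg(censored)
  if (!(dt > 0 && dt <= 0.01)) stop("'dt' must lie in (0, 0.01]", call. = FALSE)
  if (t_max <= params$t0) stop("'t_max' must exceed 't0'", call. = FALSE)
  stopifnot(n >= 1)
  m <- .simulate_trials_cpp(as.integer(n), params$v, params$a, params$zr,
                            params$t0, params$alpha, params$sv, params$szr,
                            params$st, dt, t_max,
                            if (censored == "resample") as.integer(max_attempts) else 0L)
  data.frame(choice = c("lower", "upper")[m[, 1] + 1L],
             rt = m[, 2], decision_time = m[, 3],
             stringsAsFactors = FALSE)
}

#' Simulate an epoch-structured dataset for one participant
#'
#' Simulates `n_per_epoch` trials independently for each epoch-specific
#' parameterization, mirroring the practice design in which a session is
#' analyzed as four epochs of 240 trials.
#'
#' @param params_by_epoch List of [lf_params()], one per epoch (default
#'   length 4).
#' @param n_per_epoch Trials per epoch (default 240).
#' @param participant,condition Identifiers stored in the output.
#' @param max_censored_frac Generation fails if, after resampling, more than
#'   this fraction of trials in any epoch remains censored.
#' @inheritParams simulate_trials
#' @return An `lf_data` data frame with columns
#'   `participant, condition, epoch, trial, choice, rt`.
#' @examples
#' set.seed(1)
#' p <- lapply(c(2, 1.5, 1.2, 1), function(a) lf_params(v = 1, a = a, alpha = 1.5))
#' d <- simulate_dataset(p, n_per_epoch = 20)
#' table(d$epoch)
#' @export
simulate_dataset <- function(params_by_epoch, n_per_epoch = 240,
                             participant = "p1", condition = "high",
                             dt = 0.001, t_max = 10, max_attempts = 100L,
                             max_censored_frac = 0.01) {
  stopifnot(is.list(params_by_epoch), length(params_by_epoch) >= 1,
            n_per_epoch >= 1)
  epochs <- lapply(seq_along(params_by_epoch), function(e) {
    tr <- simulate_trials(params_by_epoch[[e]], n_per_epoch, dt = dt,
                          t_max = t_max, censored = "resample",
                          max_attempts = max_attempts)
    if (mean(is.na(tr$choice)) > max_censored_frac) {
      stop(sprintf("epoch %d: censored fraction exceeds %.3f", e,
                   max_censored_frac), call. = FALSE)
    }
    data.frame(participant = participant, condition = condition, epoch = e,
               trial = seq_len(n_per_epoch), choice = tr$choice, rt = tr$rt,
               stringsAsFactors = FALSE)
  })
  as_lf_data(do.call(rbind, epochs))
}

#' @rdname simulate_dataset
#' @param x A data frame with the trial columns
#'   `participant, condition, epoch, trial, choice, rt`.
#' @export
as_lf_data <- function(x) {
  need <- c("participant", "condition", "epoch", "trial", "choice", "rt")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("lf_data", "data.frame")
  x
}

#' Simulate method for Levy-flight parameter objects
#'
#' @param object An [lf_params()] object.
#' @param nsim Number of trials.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Further arguments for [simulate_trials()].
#' @return See [simulate_trials()].
#' @export
simulate.lf_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_trials(object, n = nsim, ...)
}

# split one participant's lf_data into per-epoch data frames, epochs ordered
split_epochs <- function(data) {
  data <- data[order(data$epoch, data$trial), , drop = FALSE]
  split(data, data$epoch)
}

epoch_counts <- function(data) as.integer(table(factor(data$epoch)))
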