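#' Information criteria for response-time model fits
#'
#' Two conventions are implemented.  `convention = "paper"` reproduces the
#' arithmetic of the reference analysis's fit table: summed over
#' participants,
#' \deqn{\mathrm{AIC} = -2\log L + K, \qquad
#'   \mathrm{BIC} = -2\log L + K \ln n,}
#' where `K` is the total free-parameter count (per-participant `k` times
#' the number of participants) and `n` the per-participant trial count
#' (960).  `convention = "standard"` is the textbook form, `-2 log L + 2K`
#' and `BIC` with the total observation count across participants.
#'
#' @param logL Summed log likelihood.
#' @param k_total Total free-parameter count.
#' @param n_per_participant Trials per participant.
#' @param convention `"paper"` (default, reproduces the published table) or
#'   `"standard"`.
#' @param n_total Total observations, required for `"standard"` BIC when it
#'   differs from `n_per_participant`.
#' @return Named vector `c(AIC, BIC)`.
#' @examples
#' information_criteria(-61624, 330, 960)  # AIC 123578, BIC 125514.05
#' @export
information_criteria <- function(logL, k_total, n_per_participant,
                                 convention = c("paper", "standard"),
                                 n_total = NULL) {
  convention <- match.arg(convention)
  stopifnot(k_total >= 0, n_per_participant >= 1)
  if (convention == "paper") {
    c(AIC = -2 * logL + k_total,
      BIC = -2 * logL + k_total * log(n_per_participant))
  } else {
    n <- if (is.null(n_total)) n_per_participant else n_total
    c(AIC = -2 * logL + 2 * k_total, BIC = -2 * logL + k_total * log(n))
  }
}

#' Compare fitted model variants by likelihood, AIC and BIC
#'
#' Evaluates each model's summed log likelihood over a set of participant
#' datasets and tabulates AIC and BIC.  `fits` is a named list (one entry
#' per model variant) of lists of `"lf_fit"` objects aligned with
#' `datasets`.
#'
#' @param datasets List of per-participant `lf_data`.
#' @param fits Named list: `fits[[model]][[i]]` is the fit of participant
#'   `i` under that model.
#' @param method,n_kde,dt Passed to [log_likelihood()].
#' @param convention Passed to [information_criteria()].
#' @return An `"lf_comparison"`: data frame with one row per model
#'   (`model, logL, k_total, AIC, BIC`, best-model flags) and the
#'   per-participant log likelihoods as attribute `"per_participant"`.
#' @export
compare_models <- function(datasets, fits, method = "kde", n_kde = 1e4,
                           dt = 0.001, convention = "paper") {
  stopifnot(length(fits) >= 1, all(lengths(fits) == length(datasets)))
  n_per <- nrow(datasets[[1]])
  per <- lapply(names(fits), function(mn) {
    vapply(seq_along(datasets), function(i) {
      log_likelihood(datasets[[i]], fits[[mn]][[i]], method = method,
                     n_kde = n_kde, dt = dt)
    }, numeric(1))
  })
  names(per) <- names(fits)
  tab <- do.call(rbind, lapply(names(fits), function(mn) {
    logL <- sum(per[[mn]])
    k_total <- fits[[mn]][[1]]$model$k * length(datasets)
    ic <- information_criteria(logL, k_total, n_per, convention)
    data.frame(model = mn, logL = logL, k_total = k_total,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]],
               stringsAsFactors = FALSE)
  }))
  tab$best_logL <- tab$logL == max(tab$logL)
  tab$best_AIC <- tab$AIC == min(tab$AIC)
  tab$best_BIC <- tab$BIC == min(tab$BIC)
  attr(tab, "per_participant") <- per
  class(tab) <- c("lf_comparison", "data.frame")
  tab
}

#' @export
print.lf_comparison <- function(x, ...) {
  cat("Model comparison (", nrow(x), " variants)\n", sep = "")
  df <- as.data.frame(x)
  df$logL <- round(df$logL, 1)
  df$AIC <- round(df$AIC, 1)
  df$BIC <- round(df$BIC, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mean percent change of an epoch-indexed parameter
#'
#' For each participant, computes
#' \eqn{100\,(\theta_{epoch 4} - \theta_{epoch 1})/\theta_{epoch 1}} and
#' returns the arithmetic mean across participants.  Note this
#' mean-of-per-participant-changes differs from the percent change of the
#' mean estimates; the per-participant average is what is reported here.
#'
#' @param fits List of `"lf_fit"` objects sharing one model variant.
#' @param parameter Name of an epoch-indexed parameter (e.g. `"alpha"`).
#' @return Mean percent change (scalar).
#' @export
epoch_change_summary <- function(fits, parameter) {
  model <- fits[[1]]$model
  if (!parameter %in% model$per_epoch) {
    stop(sprintf("'%s' is not epoch-indexed in model '%s'", parameter,
                 model$name), call. = FALSE)
  }
  first <- paste0(parameter, 1)
  last <- paste0(parameter, model$n_epochs)
  ch <- vapply(fits, function(f) {
    100 * (f$estimates[[last]] - f$estimates[[first]]) / f$estimates[[first]]
  }, numeric(1))
  mean(ch)
}

#' Posterior-predictive check of a fit
#'
#' Simulates `n_sim` trials per epoch at the fitted parameters and reports
#' observed versus predicted RT quantiles (0.1, 0.3, 0.5, 0.7, 0.9; type-7
#' linear interpolation) for correct (upper) and error (lower) responses,
#' plus accuracy, per epoch.  A side with fewer than 5 observed trials has
#' its quantiles reported as `NA` rather than interpolated.
#'
#' @param data One participant's `lf_data`.
#' @param fit An `"lf_fit"`.
#' @param n_sim Simulated trials per epoch.
#' @param dt Euler step for the predictive simulations.
#' @param probs Quantile levels.
#' @return Data frame with columns `epoch, side, source, accuracy,
#'   q10, q30, q50, q70, q90`.
#' @export
predictive_check <- function(data, fit, n_sim = 1e4, dt = 0.001,
                             probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  pars_by_epoch <- theta_to_params(fit$model, fit$estimates)
  eps <- split_epochs(data)
  qcols <- paste0("q", probs * 100)
  rows <- list()
  for (e in seq_along(eps)) {
    d <- eps[[e]]
    sim <- simulate_trials(pars_by_epoch[[as.integer(names(eps)[e])]], n_sim,
                           dt = dt, censored = "flag")
    sim <- sim[!is.na(sim$choice), , drop = FALSE]
    for (src in c("observed", "predicted")) {
      dd <- if (src == "observed") d else sim
      acc <- mean(dd$choice == "upper")
      for (side in c("upper", "lower")) {
        rt <- dd$rt[dd$choice == side]
        qs <- if (length(rt) >= 5) {
          quantile(rt, probs, names = FALSE, type = 7)
        } else rep(NA_real_, length(probs))
        row <- data.frame(epoch = as.integer(names(eps)[e]), side = side,
                          source = src, accuracy = acc,
                          stringsAsFactors = FALSE)
        row[qcols] <- as.list(qs)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Predict method for Levy-flight fits
#'
#' Convenience wrapper: a predictive check of the fit against the data it
#' is paired with.
#'
#' @param object An `"lf_fit"`.
#' @param data The participant's `lf_data`.
#' @param ... Passed to [predictive_check()].
#' @export
predict.lf_fit <- function(object, data, ...) {
  predictive_check(data, object, ...)
}

#' Simulate from a fitted model
#'
#' @param object An `"lf_fit"`.
#' @param nsim Trials per epoch.
#' @param seed Optional seed.
#' @param ... Passed to [simulate_dataset()].
#' @export
simulate.lf_fit <- function(object, nsim = 240, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pars <- theta_to_params(object$model, object$estimates)
  simulate_dataset(pars, n_per_epoch = nsim,
                   participant = object$participant, ...)
}
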