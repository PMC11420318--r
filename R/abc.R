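# Per-epoch summary statistics for ABC: accuracy (upper fraction) plus the
# 0.1/0.3/0.5/0.7/0.9 RT quantiles for each response side.  A side with
# fewer than 5 trials falls back to the pooled epoch quantiles so that the
# summary vector keeps a fixed length.
abc_summaries <- function(data, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  eps <- split_epochs(data)
  unlist(lapply(eps, function(d) {
    pooled <- quantile(d$rt, probs, names = FALSE, type = 7)
    qs <- lapply(c("upper", "lower"), function(side) {
      rt <- d$rt[d$choice == side & !is.na(d$choice)]
      if (length(rt) >= 5) quantile(rt, probs, names = FALSE, type = 7)
      else pooled
    })
    c(mean(d$choice == "upper", na.rm = TRUE), qs[[1]], qs[[2]])
  }), use.names = FALSE)
}

#' Rejection-ABC parameter estimation
#'
#' Network-free reference fitter: draws `n_sims` parameter vectors from the
#' training prior, simulates a dataset for each, summarizes every dataset by
#' per-epoch accuracy and RT quantiles (0.1/0.3/0.5/0.7/0.9 per response
#' side), and returns the posterior mean of the `accept_frac` fraction of
#' draws closest to the observed summaries in standardized Euclidean
#' distance.
#'
#' @param model An [lf_model()] or model name.
#' @param data One participant's `lf_data` (equal epoch sizes).
#' @param n_sims Number of prior simulations.
#' @param accept_frac Acceptance fraction (default top 1%).
#' @param priors Prior ranges.
#' @param dt Euler step for the reference simulations.
#' @param reference Optionally, a precomputed reference table (list with
#'   `theta` and `S`) from a previous call with the same model and trial
#'   counts, to share simulations across participants.
#' @return An `"lf_fit"`; the accepted reference table is attached as
#'   attribute `"reference"` so it can be reused.
#' @export
abc_estimate <- function(model, data, n_sims = 2000, accept_frac = 0.01,
                         priors = default_priors(), dt = 0.001,
                         reference = NULL) {
  if (is.character(model)) model <- lf_model(model)
  n_per_epoch <- epoch_counts(data)[1]
  if (is.null(reference)) {
    theta <- sample_prior(model, n_sims, priors)
    S <- matrix(NA_real_, n_sims, length(abc_summaries(data)))
    for (i in seq_len(n_sims)) {
      pars <- theta_to_params(model, theta[i, ], priors)
      d <- simulate_dataset(pars, n_per_epoch, dt = dt)
      S[i, ] <- abc_summaries(d)
    }
    reference <- list(theta = theta, S = S)
  }
  obs <- abc_summaries(data)
  sds <- apply(reference$S, 2, sd)
  sds[sds < 1e-12] <- 1
  dist2 <- colSums((t(reference$S) - obs)^2 / sds^2)
  n_keep <- max(1L, floor(accept_frac * nrow(reference$theta)))
  keep <- order(dist2)[seq_len(n_keep)]
  if (!length(keep)) stop("no accepted particles", call. = FALSE)
  est <- colMeans(reference$theta[keep, , drop = FALSE])
  fit <- new_lf_fit(participant = unique(data$participant)[1],
                    model = model, estimates = est, method = "abc")
  attr(fit, "reference") <- reference
  fit
}
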