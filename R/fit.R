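#' Fit a Levy-flight model variant to one participant
#'
#' The main fitting entry point.  With `method = "network"` the fit is a
#' single deterministic forward pass through a trained amortized estimator
#' (see [lf_train()]); with `method = "abc"` it is the rejection-ABC
#' posterior mean ([abc_estimate()]).
#'
#' @param data One participant's `lf_data` with equal trials per epoch.
#' @param model An [lf_model()] or model name; ignored (taken from the
#'   estimator) when an estimator is supplied.
#' @param method `"network"` or `"abc"`.
#' @param estimator A trained `"lf_estimator"`, required for
#'   `method = "network"`.
#' @param ... Passed on to [estimate()] or [abc_estimate()].
#' @return An `"lf_fit"` object; see [coef.lf_fit()], [predict.lf_fit()],
#'   [simulate.lf_fit()], [log_likelihood()].
#' @examples
#' \donttest{
#' set.seed(7)
#' truth <- lapply(c(2, 1.6, 1.4, 1.2), function(a)
#'   lf_params(v = 1.3, a = a, t0 = 0.45, alpha = 1.4))
#' d <- simulate_dataset(truth, n_per_epoch = 60)
#' fit <- lf_fit(d, "alpha_varying", method = "abc", n_sims = 200)
#' coef(fit)
#' }
#' @export
lf_fit <- function(data, model = "alpha_varying",
                   method = c("network", "abc"), estimator = NULL, ...) {
  method <- match.arg(method)
  if (method == "network") {
    if (is.null(estimator)) {
      stop("method = 'network' needs a trained estimator; see lf_train()",
           call. = FALSE)
    }
    estimate(estimator, data, ...)
  } else {
    abc_estimate(model, data, ...)
  }
}

#' Log likelihood method for Levy-flight fits
#'
#' @param object An `"lf_fit"`.
#' @param data The participant's `lf_data` (the fit object does not carry
#'   the data).
#' @param ... Passed to [log_likelihood()].
#' @return A `"logLik"` object with `df` set to the model's free-parameter
#'   count.
#' @export
logLik.lf_fit <- function(object, data, ...) {
  ll <- log_likelihood(data, object, ...)
  structure(ll, df = object$model$k, nobs = nrow(data), class = "logLik")
}
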