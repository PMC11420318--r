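#' The five Levy-flight model variants
#'
#' Registry of the model variants compared in the practice-data analysis.
#' All five share the Levy-flight core and estimate a decision threshold per
#' trial epoch; they differ in which additional parameter is epoch-indexed:
#'
#' * `alpha_varying` - epoch-wise `a` and `alpha`; no between-trial
#'   variability (11 free parameters).
#' * `drift_variability` - single `alpha`; epoch-wise `a` and `sv` (12).
#' * `startpoint_variability` - single `alpha`; epoch-wise `a` and `szr` (12).
#' * `ndt_variability` - single `alpha`; epoch-wise `a` and `st` (12).
#' * `drift_alpha_varying` - epoch-wise `a`, `v` and `alpha` (14).
#'
#' @param name Model name (see above).
#' @param n_epochs Number of trial epochs (default 4).
#' @return An object of class `"lf_model"`: list with `name`, `shared`,
#'   `per_epoch`, `k` (free-parameter count), `n_epochs`, and `par_names`
#'   (the layout of a parameter vector: shared first, then each per-epoch
#'   parameter expanded as `name1 ... name<n_epochs>`).
#' @examples
#' lf_model("alpha_varying")$k  # 11
#' @export
lf_model <- function(name = c("alpha_varying", "drift_variability",
                              "startpoint_variability", "ndt_variability",
                              "drift_alpha_varying"),
                     n_epochs = 4L) {
  name <- match.arg(name)
  spec <- switch(name,
    alpha_varying = list(shared = c("v", "zr", "t0"),
                         per_epoch = c("a", "alpha")),
    drift_variability = list(shared = c("v", "zr", "t0", "alpha"),
                             per_epoch = c("a", "sv")),
    startpoint_variability = list(shared = c("v", "zr", "t0", "alpha"),
                                  per_epoch = c("a", "szr")),
    ndt_variability = list(shared = c("v", "zr", "t0", "alpha"),
                           per_epoch = c("a", "st")),
    drift_alpha_varying = list(shared = c("zr", "t0"),
                               per_epoch = c("a", "v", "alpha")))
  pn <- c(spec$shared,
          unlist(lapply(spec$per_epoch,
                        function(p) paste0(p, seq_len(n_epochs)))))
  structure(list(name = name, shared = spec$shared,
                 per_epoch = spec$per_epoch,
                 k = length(pn), n_epochs = as.integer(n_epochs),
                 par_names = pn),
            class = "lf_model")
}

#' @export
print.lf_model <- function(x, ...) {
  cat(sprintf("Levy-flight model variant '%s' (%d free parameters)\n",
              x$name, x$k))
  cat("  shared:    ", paste(x$shared, collapse = ", "), "\n")
  cat("  per epoch: ", paste(x$per_epoch, collapse = ", "),
      sprintf(" (%d epochs)\n", x$n_epochs))
  invisible(x)
}

#' @rdname lf_model
#' @export
lf_model_names <- function() {
  c("alpha_varying", "drift_variability", "startpoint_variability",
    "ndt_variability", "drift_alpha_varying")
}

#' Default training prior ranges
#'
#' Uniform ranges used both as the training prior of the amortized estimator
#' and as the ABC prior.  They are chosen to cover the parameter regime of
#' practice data in the motion-discrimination task (thresholds up to 7 early
#' in practice, drift 0.3-3.5, alpha over its full \[1, 2\] range).
#'
#' @return Named list of `c(lower, upper)` ranges for
#'   `v, a, zr, t0, alpha, sv, szr, st`.
#' @export
default_priors <- function() {
  list(v = c(0.3, 3.5), a = c(0.3, 7), zr = c(0.3, 0.7), t0 = c(0.15, 0.8),
       alpha = c(1, 2), sv = c(0, 2), szr = c(0, 0.6), st = c(0, 0.6))
}

# map a (possibly epoch-suffixed) parameter name to its base name;
# "t0" is a base name itself, not an epoch index
par_base <- function(nm) {
  ifelse(nm %in% c("v", "a", "zr", "t0", "alpha", "sv", "szr", "st"),
         nm, sub("[0-9]+$", "", nm))
}

#' Draw parameter vectors from the training prior
#'
#' Independent uniforms over [default_priors()] ranges, with two joint
#' constraints enforced by shrinking the variability draw: `szr` is capped
#' at `2 min(zr, 1 - zr) - 0.02` (start window inside (0, 1)) and `st` at
#' `2 t0` (non-decision time non-negative).
#'
#' @param model An [lf_model()].
#' @param n Number of draws.
#' @param priors Prior ranges, as from [default_priors()].
#' @return `n x k` matrix with columns `model$par_names`.
#' @export
sample_prior <- function(model, n, priors = default_priors()) {
  stopifnot(inherits(model, "lf_model"))
  th <- matrix(NA_real_, n, model$k, dimnames = list(NULL, model$par_names))
  for (nm in model$par_names) {
    r <- priors[[par_base(nm)]]
    th[, nm] <- runif(n, r[1], r[2])
  }
  th <- enforce_constraints(th)
  th
}

enforce_constraints <- function(th) {
  zr <- if ("zr" %in% colnames(th)) th[, "zr"] else 0.5
  t0 <- if ("t0" %in% colnames(th)) th[, "t0"] else Inf
  for (nm in colnames(th)) {
    base <- par_base(nm)
    if (base == "szr") {
      th[, nm] <- pmin(th[, nm], pmax(2 * pmin(zr, 1 - zr) - 0.02, 0))
    } else if (base == "st") {
      th[, nm] <- pmin(th[, nm], 2 * t0)
    }
  }
  th
}

# Expand row `theta` (named by model$par_names) into one lf_params per epoch.
theta_to_params <- function(model, theta, priors = default_priors()) {
  stopifnot(length(theta) == model$k)
  names(theta) <- model$par_names
  lapply(seq_len(model$n_epochs), function(e) {
    val <- function(base) {
      if (base %in% model$shared) theta[[base]]
      else if (base %in% model$per_epoch) theta[[paste0(base, e)]]
      else 0
    }
    lf_params(v = val("v"), a = val("a"), zr = val("zr"), t0 = val("t0"),
              alpha = val("alpha"), sv = val("sv"), szr = val("szr"),
              st = val("st"))
  })
}

# min-max normalization of parameter vectors to [0, 1] per the prior ranges
normalize_theta <- function(th, priors = default_priors()) {
  for (nm in colnames(th)) {
    r <- priors[[par_base(nm)]]
    th[, nm] <- (th[, nm] - r[1]) / (r[2] - r[1])
  }
  th
}

denormalize_theta <- function(th, priors = default_priors()) {
  for (nm in colnames(th)) {
    r <- priors[[par_base(nm)]]
    th[, nm] <- pmin(pmax(th[, nm], 0), 1) * (r[2] - r[1]) + r[1]
  }
  th
}
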