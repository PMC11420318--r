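#' Configuration for amortized estimator training
#'
#' Defaults mirror the reference analysis: 28000 simulated training
#' datasets of 240 trials per epoch, a five-layer convolutional network with
#' filter counts 64, 64, 128, 128, 128, and one input channel per trial
#' epoch.  For continuous-integration scale work a reduced
#' `n_datasets` (e.g. 4000) with the same architecture is the intended
#' setting; see the package vignette.
#'
#' @param n_datasets Number of simulated training datasets.
#' @param trials_per_epoch Trials per epoch in each dataset.
#' @param n_epochs Trial epochs (input channels).
#' @param priors Uniform prior ranges, as [default_priors()].
#' @param filters Filter counts per convolutional layer.
#' @param kernel Convolution kernel widths (odd), one per layer or a single
#'   shared width (default 9: wide kernels help because the channels are
#'   sorted response times, so neighborhoods are quantile bands).
#' @param dt Euler step for the training simulations (s).
#' @param epochs_train Maximum optimizer passes over the training set.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay.
#' @param val_frac Held-out fraction for early stopping.
#' @param patience Early-stopping patience (epochs without improvement).
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(n_datasets = 28000, trials_per_epoch = 240,
                            n_epochs = 4L, priors = default_priors(),
                            filters = c(64, 64, 128, 128, 128),
                            kernel = 9L,
                            dt = 0.001, epochs_train = 30L, batch = 32L,
                            lr = 1e-3, lr_decay = 0.95, val_frac = 0.1,
                            patience = 3L) {
  stopifnot(n_datasets >= 10, trials_per_epoch >= 8, all(kernel %% 2 == 1),
            length(kernel) %in% c(1L, length(filters)))
  structure(list(n_datasets = n_datasets,
                 trials_per_epoch = as.integer(trials_per_epoch),
                 n_epochs = as.integer(n_epochs), priors = priors,
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 dt = dt, epochs_train = as.integer(epochs_train),
                 batch = as.integer(batch), lr = lr, lr_decay = lr_decay,
                 val_frac = val_frac, patience = as.integer(patience)),
            class = "training_config")
}

# Simulate a prior-predictive training set: encoded datasets (rows) plus
# the generating parameters.  Censored trials are resampled (generator
# semantics); the rare dataset that still fails is redrawn.
make_training_set <- function(model, cfg, n = cfg$n_datasets) {
  theta <- sample_prior(model, n, cfg$priors)
  X <- matrix(NA_real_, n, cfg$n_epochs * cfg$trials_per_epoch)
  for (i in seq_len(n)) {
    repeat {
      pars <- theta_to_params(model, theta[i, ], cfg$priors)
      d <- tryCatch(simulate_dataset(pars, cfg$trials_per_epoch, dt = cfg$dt),
                    error = function(e) NULL)
      if (!is.null(d)) break
      theta[i, ] <- sample_prior(model, 1, cfg$priors)
    }
    X[i, ] <- as.vector(encode_dataset(d))
  }
  list(X = X, theta = theta)
}

#' Train an amortized estimator for one model variant
#'
#' Simulates `cfg$n_datasets` datasets with parameters drawn from the
#' uniform training prior, encodes each as sorted choice-signed response
#' times (one channel per epoch), and trains the convolutional regression
#' network to predict the min-max-normalized generating parameters by
#' minimizing mean squared error (Adam, early stopping on a held-out
#' split).  Once trained, estimating any new dataset is a single forward
#' pass - the simulation cost is amortized.
#'
#' Randomness (simulation, initialization, minibatch order) is governed by
#' R's RNG; call [set.seed()] beforehand for reproducible training.
#'
#' @param model An [lf_model()] or model name.
#' @param cfg A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `"lf_estimator"`.
#' @export
lf_train <- function(model, cfg = training_config(), verbose = FALSE) {
  if (is.character(model)) model <- lf_model(model, cfg$n_epochs)
  ts <- make_training_set(model, cfg)
  Y <- normalize_theta(ts$theta, cfg$priors)
  n_val <- max(1L, floor(cfg$val_frac * nrow(ts$X)))
  fit <- .cnn_train_cpp(ts$X, Y, cfg$n_epochs, cfg$trials_per_epoch,
                        cfg$filters, cfg$kernel, cfg$epochs_train, cfg$batch,
                        cfg$lr, cfg$lr_decay, n_val, cfg$patience,
                        isTRUE(verbose))
  structure(list(weights = fit[c("W", "b", "Wd", "bd", "kernel")],
                 model = model, priors = cfg$priors,
                 trials_per_epoch = cfg$trials_per_epoch,
                 n_epochs = cfg$n_epochs,
                 train_loss = fit$train_loss, val_loss = fit$val_loss),
            class = "lf_estimator")
}

#' @export
print.lf_estimator <- function(x, ...) {
  cat(sprintf("Amortized estimator for '%s' (%d parameters)\n",
              x$model$name, x$model$k))
  cat(sprintf("  input: %d channels x %d trials; final val MSE %.5f\n",
              x$n_epochs, x$trials_per_epoch,
              tail_finite(x$val_loss)))
  invisible(x)
}

tail_finite <- function(x) {
  x <- x[is.finite(x)]
  if (length(x)) x[length(x)] else NA_real_
}

#' Predict parameters with a trained estimator
#'
#' A deterministic forward pass through the trained network; outputs are
#' clipped to the prior support.
#'
#' @param object An `"lf_estimator"`.
#' @param newdata An `lf_data` data frame for one participant, or an
#'   encoded matrix/row-matrix from [encode_dataset()].
#' @param ... Unused.
#' @return Named numeric vector (single dataset) or matrix of estimates.
#' @export
predict.lf_estimator <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata) &&
           ncol(newdata) == object$n_epochs * object$trials_per_epoch) {
    newdata                        # rows of flattened encodings
  } else if (is.matrix(newdata) && nrow(newdata) == object$n_epochs &&
             ncol(newdata) == object$trials_per_epoch) {
    matrix(as.vector(newdata), 1)  # a single encoded dataset
  } else {
    enc <- encode_dataset(newdata)
    if (ncol(enc) != object$trials_per_epoch) {
      stop(sprintf("dataset has %d trials per epoch; estimator expects %d",
                   ncol(enc), object$trials_per_epoch), call. = FALSE)
    }
    matrix(as.vector(enc), 1)
  }
  raw <- .cnn_predict_cpp(object$weights, X, object$n_epochs,
                          object$trials_per_epoch)
  colnames(raw) <- object$model$par_names
  est <- denormalize_theta(raw, object$priors)
  est <- enforce_constraints(est)
  if (nrow(est) == 1L) est[1, ] else est
}

#' Estimate model parameters for one participant
#'
#' @param estimator A trained `"lf_estimator"`.
#' @param data One participant's `lf_data`.
#' @param bootstrap Number of within-epoch trial resamples for nonparametric
#'   uncertainty (0 = none).
#' @return An `"lf_fit"` object: participant id, model, named estimates,
#'   and bootstrap SDs when requested.
#' @export
estimate <- function(estimator, data, bootstrap = 0L) {
  stopifnot(inherits(estimator, "lf_estimator"))
  est <- predict(estimator, data)
  se <- NULL
  if (bootstrap > 0L) {
    reps <- vapply(seq_len(bootstrap), function(r) {
      eps <- split_epochs(data)
      res <- do.call(rbind, lapply(eps, function(d) {
        d[sample.int(nrow(d), replace = TRUE), , drop = FALSE]
      }))
      predict(estimator, as_lf_data(res))
    }, numeric(estimator$model$k))
    se <- apply(reps, 1, sd)
    names(se) <- estimator$model$par_names
  }
  new_lf_fit(participant = unique(data$participant)[1],
             model = estimator$model, estimates = est, se = se,
             method = "network")
}

new_lf_fit <- function(participant, model, estimates, se = NULL,
                       method = "network") {
  stopifnot(length(estimates) == model$k)
  structure(list(participant = participant, model = model,
                 estimates = estimates, se = se, method = method),
            class = "lf_fit")
}

#' @export
print.lf_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Levy-flight fit ('%s', %s) for participant %s\n",
              x$model$name, x$method, x$participant))
  print(round(x$estimates, digits))
  invisible(x)
}

#' @export
coef.lf_fit <- function(object, ...) object$estimates

#' Serialize a trained estimator
#'
#' Writes the network weights as a flat binary vector of doubles with a
#' JSON sidecar recording the model variant, prior ranges, input shape and
#' layer dimensions, so the pair fully reconstructs the estimator.
#'
#' @param estimator An `"lf_estimator"`.
#' @param bin_path Path for the binary weight file.
#' @param json_path Path for the JSON sidecar (default: `bin_path` +
#'   `.json`).
#' @return `bin_path`, invisibly.
#' @export
write_estimator <- function(estimator, bin_path,
                            json_path = paste0(bin_path, ".json")) {
  w <- estimator$weights
  mats <- c(w$W, w$b, list(w$Wd, w$bd))
  flat <- unlist(lapply(mats, as.numeric))
  writeBin(flat, bin_path, size = 8, endian = "little")
  meta <- list(model = estimator$model$name,
               n_epochs = estimator$n_epochs,
               trials_per_epoch = estimator$trials_per_epoch,
               kernel = w$kernel,
               dims = lapply(mats, dim),
               n_conv = length(w$W),
               priors = estimator$priors,
               train_loss = estimator$train_loss,
               val_loss = estimator$val_loss)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(bin_path)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(bin_path, json_path = paste0(bin_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dims <- meta$dims
  if (is.matrix(dims)) dims <- lapply(seq_len(nrow(dims)), function(i) dims[i, ])
  n_el <- sum(vapply(dims, prod, numeric(1)))
  flat <- readBin(bin_path, "double", n = n_el, size = 8, endian = "little")
  mats <- vector("list", length(dims))
  off <- 0L
  for (i in seq_along(dims)) {
    sz <- prod(dims[[i]])
    mats[[i]] <- matrix(flat[(off + 1):(off + sz)], dims[[i]][1], dims[[i]][2])
    off <- off + sz
  }
  nc <- meta$n_conv
  weights <- list(W = mats[seq_len(nc)], b = mats[nc + seq_len(nc)],
                  Wd = mats[[2 * nc + 1]], bd = mats[[2 * nc + 2]],
                  kernel = meta$kernel)
  model <- lf_model(meta$model, meta$n_epochs)
  priors <- lapply(meta$priors, as.numeric)
  structure(list(weights = weights, model = model, priors = priors,
                 trials_per_epoch = meta$trials_per_epoch,
                 n_epochs = meta$n_epochs,
                 train_loss = meta$train_loss, val_loss = meta$val_loss),
            class = "lf_estimator")
}
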