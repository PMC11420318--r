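# Trained estimators are expensive; train each at most once per test run and
# share across test files.  The study-scale network (alpha-varying variant,
# 4000 training sets of 4 x 240 trials, seed 1234) backs both the recovery
# and the model-recovery checks; the four control-variant networks use a
# smaller budget (600 training sets), enough for plausible fits in the
# model-recovery ranking.

.estimator_cache <- new.env(parent = emptyenv())

study_scale_config <- function(n_datasets = 4000) {
  training_config(n_datasets = n_datasets, trials_per_epoch = 240,
                  epochs_train = 25, patience = 3)
}

get_study_estimator <- function() {
  if (is.null(.estimator_cache$alpha_varying)) {
    set.seed(1234)
    .estimator_cache$alpha_varying <-
      lf_train("alpha_varying", study_scale_config())
  }
  .estimator_cache$alpha_varying
}

get_control_estimator <- function(name) {
  if (is.null(.estimator_cache[[name]])) {
    set.seed(1234 + match(name, lf_model_names()))
    cfg <- training_config(n_datasets = 300, trials_per_epoch = 240,
                           epochs_train = 12, patience = 4)
    .estimator_cache[[name]] <- lf_train(name, cfg)
  }
  .estimator_cache[[name]]
}

# small estimator for interface-level tests (32 trials/epoch)
get_toy_estimator <- function() {
  if (is.null(.estimator_cache$toy)) {
    set.seed(99)
    cfg <- training_config(n_datasets = 250, trials_per_epoch = 32,
                           epochs_train = 4, patience = 2)
    .estimator_cache$toy <- lf_train("alpha_varying", cfg)
  }
  .estimator_cache$toy
}
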