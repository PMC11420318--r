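TRIAL_HEADER <- c("participant", "condition", "epoch", "trial", "choice", "rt")

#' Write and read trial data as CSV
#'
#' The trial CSV dialect has header
#' `participant,condition,epoch,trial,choice,rt`, choice coded
#' `upper`/`lower`, and RT in seconds with six decimal digits.
#' `read_trials()` validates on input: malformed or non-positive RTs and
#' unknown choice codes are rejected with their line numbers (line 1 is the
#' header).
#'
#' @param data An `lf_data` (any number of participants).
#' @param path File path.
#' @return `write_trials()`: the path, invisibly.  `read_trials()`: a list
#'   of per-participant `lf_data` data frames with epochs ordered; an empty
#'   file with a valid header gives an empty list with a warning.
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "data.frame"))
  out <- data[, TRIAL_HEADER]
  out$rt <- sprintf("%.6f", out$rt)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(rt = "character", epoch = "character"))
  if (!identical(names(raw), TRIAL_HEADER)) {
    stop("header must be exactly '", paste(TRIAL_HEADER, collapse = ","),
         "'", call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("no trial rows in ", path, call. = FALSE)
    return(list())
  }
  line <- seq_len(nrow(raw)) + 1L
  rt <- suppressWarnings(as.numeric(raw$rt))
  epoch <- suppressWarnings(as.integer(raw$epoch))
  bad <- which(is.na(rt) | rt <= 0)
  if (length(bad)) {
    stop("non-positive or malformed rt on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!(raw$choice %in% c("upper", "lower")))
  if (length(bad)) {
    stop("choice must be 'upper' or 'lower' on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(epoch) | epoch < 1)
  if (length(bad)) {
    stop("malformed epoch on line(s) ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  }
  raw$rt <- rt
  raw$epoch <- epoch
  ids <- unique(raw$participant)
  out <- lapply(ids, function(id) {
    d <- raw[raw$participant == id, , drop = FALSE]
    as_lf_data(d[order(d$epoch, d$trial), , drop = FALSE])
  })
  names(out) <- ids
  out
}

#' Pipeline configuration
#'
#' One source of truth for an end-to-end run: synthetic-study settings,
#' fitting method and budget, and comparison settings.  Unknown keys in any
#' block are rejected before computation starts, and every stochastic stage
#' derives its seed from `seed`, so a rerun with the same configuration
#' reproduces every output file.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param models Model variants to fit.
#' @param study Overrides for [study_config()] arguments.
#' @param fit List: `method` (`"abc"` or `"network"`), `n_sims` and
#'   `accept_frac` for ABC, or `training` overrides for
#'   [training_config()] plus optional `estimators` (pre-trained, named by
#'   model).
#' @param compare List: `n_kde`, `convention`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("lf_run_"),
                            models = lf_model_names(), study = list(),
                            fit = list(method = "abc", n_sims = 300,
                                       accept_frac = 0.05),
                            compare = list(n_kde = 5000,
                                           convention = "paper")) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(study, names(formals(study_config)), "study")
  check_keys(fit, c("method", "n_sims", "accept_frac", "training",
                    "estimators"), "fit")
  check_keys(compare, c("n_kde", "convention", "method"), "compare")
  stopifnot(all(models %in% lf_model_names()))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 models = models, study = study, fit = fit,
                 compare = compare),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes generate -> exclude -> (train) -> fit (all requested model
#' variants) -> compare -> report.  Every stage writes its outputs as it
#' completes (`trials.csv`, `ground_truth.csv`, `exclusions.csv`,
#' `fits_<model>.csv`, `comparison.csv`, `manifest.json`), so a failing
#' stage leaves the earlier artifacts on disk and aborts with the stage
#' name.
#'
#' @param cfg A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  set.seed(cfg$seed)
  st <- stage("generate", {
    sc <- do.call(study_config, cfg$study)
    generate_study(sc)
  })
  write_trials(st$data, file.path(cfg$out_dir, "trials.csv"))
  write.csv(st$ground_truth, file.path(cfg$out_dir, "ground_truth.csv"),
            row.names = FALSE)

  ex <- stage("exclude", apply_exclusion(st$data,
                                         st$config$exclusion_threshold))
  write.csv(ex$report, file.path(cfg$out_dir, "exclusions.csv"),
            row.names = FALSE)
  datasets <- split(ex$data, ex$data$participant)
  datasets <- lapply(datasets, as_lf_data)

  method <- cfg$fit$method %||% "abc"
  estimators <- cfg$fit$estimators
  if (method == "network" && is.null(estimators)) {
    estimators <- stage("train", {
      tcfg <- do.call(training_config,
                      c(cfg$fit$training,
                        list(trials_per_epoch = st$config$trials_per_epoch,
                             n_epochs = st$config$n_epochs)))
      es <- lapply(cfg$models, function(mn) {
        set.seed(cfg$seed + match(mn, lf_model_names()))
        lf_train(mn, tcfg)
      })
      names(es) <- cfg$models
      es
    })
  }

  fits <- stage("fit", {
    out <- lapply(cfg$models, function(mn) {
      set.seed(cfg$seed + 100L + match(mn, lf_model_names()))
      if (method == "network") {
        lapply(datasets, function(d) estimate(estimators[[mn]], d))
      } else {
        ref <- NULL
        lapply(datasets, function(d) {
          f <- abc_estimate(mn, d, n_sims = cfg$fit$n_sims %||% 300,
                            accept_frac = cfg$fit$accept_frac %||% 0.05,
                            reference = ref)
          ref <<- attr(f, "reference")
          f
        })
      }
    })
    names(out) <- cfg$models
    out
  })
  for (mn in cfg$models) {
    ftab <- do.call(rbind, lapply(fits[[mn]], function(f) {
      data.frame(participant = f$participant, model = mn,
                 parameter = names(f$estimates),
                 estimate = as.numeric(f$estimates),
                 stringsAsFactors = FALSE)
    }))
    write.csv(ftab, file.path(cfg$out_dir, paste0("fits_", mn, ".csv")),
              row.names = FALSE)
  }

  comp <- stage("compare", {
    set.seed(cfg$seed + 1000L)
    compare_models(datasets, fits, method = cfg$compare$method %||% "kde",
                   n_kde = cfg$compare$n_kde %||% 5000,
                   convention = cfg$compare$convention %||% "paper")
  })
  write.csv(as.data.frame(comp), file.path(cfg$out_dir, "comparison.csv"),
            row.names = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("levydm")),
                   r_version = R.version.string,
                   seed = cfg$seed, models = cfg$models,
                   n_participants = length(datasets),
                   method = method, timings_s = timings,
                   total_s = as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
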