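#' Encode an epoch-structured dataset for the summary network
#'
#' Maps one participant's trials to the fixed-shape array the convolutional
#' estimator consumes: one channel per trial epoch, each channel the vector
#' of choice-signed response times (positive for upper-boundary responses,
#' negative for lower), sorted in ascending order.  Sorting makes the
#' encoding invariant to trial order; the sign carries the choice.
#'
#' @param data An `lf_data` data frame for a single participant with equal
#'   trial counts per epoch.
#' @return Numeric matrix, `n_epochs` rows (channels) by trials-per-epoch
#'   columns.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(list(lf_params(v = 1, a = 1)), n_per_epoch = 8)
#' encode_dataset(d)
#' @export
encode_dataset <- function(data) {
  counts <- epoch_counts(data)
  if (length(unique(counts)) != 1L) {
    stop("all epochs must have the same number of trials", call. = FALSE)
  }
  if (anyNA(data$choice) || anyNA(data$rt)) {
    stop("encoding requires complete (non-censored) trials", call. = FALSE)
  }
  eps <- split_epochs(data)
  out <- t(vapply(eps, function(d) {
    sort(ifelse(d$choice == "upper", d$rt, -d$rt))
  }, numeric(counts[1])))
  dimnames(out) <- NULL
  out
}
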