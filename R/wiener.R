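#' Wiener first-passage-time quantities (the alpha = 2 limit)
#'
#' Closed-form series for the two-boundary Wiener process with unit
#' diffusion, drift `v`, boundaries at 0 and `a`, start `z = zr * a`.  These
#' are the exact distributions the Levy-flight model reduces to at
#' `alpha = 2` and serve as analytic references for the simulator, the
#' fractional solver, and likelihood code.
#'
#' `wiener_fpt_density()` evaluates the defective first-passage density at
#' the requested boundary, switching between the short-time reflection
#' (image) series and the long-time eigenfunction series at
#' \eqn{t/a^2 = 0.12}.  `wiener_absorb_prob()` is
#' \eqn{(1 - e^{-2 v z})/(1 - e^{-2 v a})} for the upper boundary, and
#' `wiener_survival()` integrates the eigenfunction series analytically.
#'
#' @param t Vector of decision times (s), `t >= 0`.
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param zr Relative start point in (0, 1).
#' @param boundary `"upper"` or `"lower"`.
#' @return Density, probability, or survival values.
#' @examples
#' wiener_absorb_prob(v = 1, a = 1, zr = 0.5)  # 0.7311
#' @export
wiener_fpt_density <- function(t, v, a, zr = 0.5,
                               boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  z <- zr * a
  if (boundary == "upper") { v <- -v; z <- a - z }  # reflect to lower-hit form
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    trel <- ti / a^2
    if (trel < 0.12) {
      j <- -7:7
      s <- sum((z + 2 * j * a) * exp(-(z + 2 * j * a)^2 / (2 * ti)))
      exp(-v * z - v^2 * ti / 2) / sqrt(2 * pi * ti^3) * s
    } else {
      K <- min(200L, max(8L, ceiling(a * sqrt(2 * 41 / ti) / pi) + 3L))
      k <- seq_len(K)
      s <- sum(k * sin(k * pi * z / a) * exp(-k^2 * pi^2 * ti / (2 * a^2)))
      pi / a^2 * exp(-v * z - v^2 * ti / 2) * s
    }
  }, numeric(1))
}

#' @rdname wiener_fpt_density
#' @export
wiener_absorb_prob <- function(v, a, zr = 0.5,
                               boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  z <- zr * a
  p_up <- if (abs(v) < 1e-12) z / a else expm1(-2 * v * z) / expm1(-2 * v * a)
  if (boundary == "upper") p_up else 1 - p_up
}

#' @rdname wiener_fpt_density
#' @export
wiener_survival <- function(t, v, a, zr = 0.5) {
  z <- zr * a
  vapply(t, function(ti) {
    if (ti <= 0) return(1)
    K <- min(3000L, max(12L, ceiling(a * sqrt(2 * 41 / ti) / pi) + 5L))
    k <- seq_len(K)
    lam <- v^2 / 2 + k^2 * pi^2 / (2 * a^2)
    term <- k / lam * exp(-lam * ti) *
      (sin(k * pi * z / a) * exp(-v * z) +
         sin(k * pi * (a - z) / a) * exp(v * (a - z)))
    min(1, max(0, pi / a^2 * sum(term)))
  }, numeric(1))
}

# Exact log likelihood in the Gaussian limit (alpha = 2, no between-trial
# variability): sum of log defective densities at rt - t0.
wiener_log_likelihood <- function(data, params, floor = 1e-10) {
  params <- as_lf_params(params)
  td <- data$rt - params$t0
  g <- numeric(nrow(data))
  for (side in c("upper", "lower")) {
    i <- which(data$choice == side & td > 0)
    if (length(i)) {
      g[i] <- wiener_fpt_density(td[i], params$v, params$a, params$zr, side)
    }
  }
  sum(log(pmax(g, floor)))
}
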