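#' Levy-flight decision-process parameters
#'
#' One parameterization of the decision process.  Units: drift in evidence/s,
#' boundary separation in evidence units, times in seconds; the start point
#' is relative, `zr = z / a`.
#'
#' @param v Mean drift rate (evidence/s).  Its sign sets the favored boundary.
#' @param a Boundary separation (> 0).  Psychologically, response caution.
#' @param zr Relative start point `z / a`, in (0, 1); 0.5 is unbiased.
#' @param t0 Mean non-decision time (s), encoding plus motor time.
#' @param alpha Stability index of the accumulation noise, in \[1, 2\];
#'   `alpha = 2` recovers the Gaussian diffusion decision model, lower values
#'   allow heavy-tailed jumps.
#' @param sv Between-trial drift SD; per-trial drift is Normal(`v`, `sv`).
#' @param szr Between-trial start-point range (relative scale); per-trial
#'   start is Uniform(`zr - szr/2`, `zr + szr/2`).
#' @param st Between-trial non-decision range (s); per-trial non-decision
#'   time is Uniform(`t0 - st/2`, `t0 + st/2`).
#' @return An object of class `"lf_params"`.
#' @examples
#' lf_params(v = 1, a = 1.5, alpha = 1.4)
#' @export
lf_params <- function(v, a, zr = 0.5, t0 = 0.3, alpha = 2,
                      sv = 0, szr = 0, st = 0) {
  vals <- c(v = v, a = a, zr = zr, t0 = t0, alpha = alpha,
            sv = sv, szr = szr, st = st)
  if (anyNA(vals)) stop("parameters must be non-missing", call. = FALSE)
  if (a <= 0) stop("'a' must be positive", call. = FALSE)
  if (zr <= 0 || zr >= 1) stop("'zr' must lie in (0, 1)", call. = FALSE)
  if (t0 < 0) stop("'t0' must be non-negative", call. = FALSE)
  if (alpha < 1 || alpha > 2) stop("'alpha' must lie in [1, 2]", call. = FALSE)
  if (sv < 0 || szr < 0 || st < 0) {
    stop("variability parameters must be non-negative", call. = FALSE)
  }
  if (zr - szr / 2 <= 0 || zr + szr / 2 >= 1) {
    stop("'zr' +/- 'szr'/2 must stay within (0, 1)", call. = FALSE)
  }
  if (t0 - st / 2 < 0) {
    stop("'t0' - 'st'/2 must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "lf_params")
}

#' @export
print.lf_params <- function(x, ...) {
  cat("Levy-flight process parameters\n")
  cat(sprintf("  v = %.3f  a = %.3f  zr = %.3f  t0 = %.3f  alpha = %.3f\n",
              x$v, x$a, x$zr, x$t0, x$alpha))
  if (x$sv > 0 || x$szr > 0 || x$st > 0) {
    cat(sprintf("  between-trial: sv = %.3f  szr = %.3f  st = %.3f\n",
                x$sv, x$szr, x$st))
  }
  invisible(x)
}

as_lf_params <- function(x) {
  if (inherits(x, "lf_params")) return(x)
  do.call(lf_params, as.list(x))
}
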