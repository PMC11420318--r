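#' Solve the space-fractional Fokker-Planck equation of the decision process
#'
#' Solves
#' \deqn{\partial_t p(x,t) + v\,\partial_x p(x,t) =
#'   \gamma^\alpha D_x^\alpha p(x,t)}
#' on the evidence interval \[0, a\] with absorbing conditions
#' \eqn{p(0,t) = p(a,t) = 0} and a delta initial condition at the start
#' point \eqn{z = z_r a}.  \eqn{D_x^\alpha} is the Riesz fractional
#' derivative, \eqn{-\frac{1}{2\cos(\alpha\pi/2)}} times the sum of the left
#' and right Riemann-Liouville derivatives; the noise-scale factor
#' \eqn{\gamma^\alpha = 2^{-\alpha/2}} matches the accumulation noise
#' \eqn{\mathrm{Stable}(\alpha,0,1/\sqrt2,0)}, so that at \eqn{\alpha = 2}
#' the right-hand side reduces to \eqn{\frac{1}{2}\partial_x^2 p}
#' (unit-variance diffusion).
#'
#' Discretization: shifted Grunwald-Letnikov weights for the two
#' Riemann-Liouville derivatives, first-order upwind differencing for the
#' drift, implicit Euler in time (unconditionally stable).  Density is
#' forced to zero on all exterior nodes (killed-on-exit), matching the
#' simulator's absorb-on-crossing rule for jump processes; the mass each
#' step deposits beyond either end is credited to that boundary, giving the
#' defective first-passage densities as a by-product.
#'
#' Requires `1 < alpha <= 2`: at `alpha = 1` the Riesz prefactor
#' \eqn{-1/(2\cos(\alpha\pi/2))} is singular.
#'
#' @param params An [lf_params()] object (between-trial variability is
#'   ignored here; see [fpde_fpt()] for quadrature over `sv`/`szr`).
#' @param nx Number of grid intervals on \[0, a\] (`nx >= 50`).
#' @param nt Number of time steps.
#' @param T Time horizon (s), decision-time scale (non-decision time plays
#'   no role in the evidence density).
#' @return An object of class `"lf_grid"`: list with `x` (nx+1 nodes),
#'   `t` (nt+1 times), `p` (density matrix, nodes x times, boundary rows
#'   zero), `g_upper`, `g_lower` (exit densities at `t`), and `params`.
#' @examples
#' g <- fpde_solve(lf_params(v = 1, a = 1, alpha = 1.5), nx = 60, nt = 60, T = 2)
#' survival(g)[1]  # 1: all mass starts inside
#' @export
fpde_solve <- function(params, nx = 200, nt = 800, T = 3) {
  params <- as_lf_params(params)
  if (params$alpha <= 1) {
    stop("fpde_solve requires alpha > 1 (Riesz prefactor singular at 1)",
         call. = FALSE)
  }
  if (nx < 50) stop("'nx' must be at least 50", call. = FALSE)
  if (nt < 1 || T <= 0) stop("invalid time grid", call. = FALSE)
  alpha <- params$alpha; a <- params$a; v <- params$v
  h <- a / nx
  M <- nx - 1L                      # interior nodes x_i = i h, i = 1..M
  dt <- T / nt

  # Grunwald-Letnikov weights g_k = (-1)^k choose(alpha, k), recursively
  gw <- numeric(M + 2L)
  gw[1] <- 1
  for (k in seq_len(M + 1L)) gw[k + 1L] <- gw[k] * (k - 1 - alpha) / k
  cfrac <- -1 / (2 * cos(alpha * pi / 2)) * (1 / sqrt(2))^alpha / h^alpha

  # shifted GL: left derivative row i uses p_{i-k+1}, right uses p_{i+k-1}
  idx <- outer(seq_len(M), seq_len(M), function(i, j) i - j + 2L) # k+1 for left
  L_left <- matrix(0, M, M)
  sel <- idx >= 1L & idx <= M + 2L
  L_left[sel] <- gw[idx[sel]]
  A <- cfrac * (L_left + t(L_left))          # right operator is the transpose

  # killing rates into each exterior side (column deficits of the truncated
  # operator); tail sums of gw are -cumsum since the full series sums to 0
  csum <- cumsum(gw)                         # csum[j+1] = sum_{k=0}^{j} g_k
  j <- seq_len(M)
  k_low <- cfrac * ((j == 1L) * gw[1] - csum[pmin(j + 1L, M + 2L)])
  k_up  <- cfrac * ((j == M)  * gw[1] - csum[pmin(M - j + 2L, M + 2L)])

  # upwind drift; outflow through the downstream end joins the killing rate
  if (v >= 0) {
    A <- A - diag(v / h, M)
    if (M > 1L) A[cbind(2:M, 1:(M - 1L))] <- A[cbind(2:M, 1:(M - 1L))] + v / h
    k_up[M] <- k_up[M] + v / h
  } else {
    A <- A + diag(v / h, M)
    if (M > 1L) A[cbind(1:(M - 1L), 2:M)] <- A[cbind(1:(M - 1L), 2:M)] - v / h
    k_low[1] <- k_low[1] - v / h
  }

  # delta initial condition at the node nearest z = zr a
  i0 <- min(max(1L, round(params$zr * nx)), M)
  p <- numeric(M); p[i0] <- 1 / h

  step <- solve(diag(M) - dt * A)            # implicit Euler propagator
  P <- matrix(0, M, nt + 1L)
  g_up <- g_lo <- numeric(nt + 1L)
  P[, 1] <- p
  for (n in seq_len(nt)) {
    p <- step %*% p
    P[, n + 1L] <- p
    g_up[n + 1L] <- sum(k_up * p) * h        # exit density (mass/time)
    g_lo[n + 1L] <- sum(k_low * p) * h
  }
  P[P < 0 & P > -1e-12] <- 0                 # clip discretization noise

  full <- rbind(0, P, 0)                     # boundary rows exactly zero
  structure(list(x = seq(0, a, length.out = nx + 1L),
                 t = seq(0, T, length.out = nt + 1L),
                 p = full, g_upper = g_up, g_lower = g_lo,
                 params = params, h = h, dt = dt),
            class = "lf_grid")
}

#' Flatten a density grid for CSV export
#'
#' Long-format view of a solved evidence-density grid, one row per
#' (x, t) node, suitable for `write.csv()`.
#'
#' @param x An `"lf_grid"` from [fpde_solve()].
#' @param row.names,optional,... Ignored (data-frame method signature).
#' @return Data frame with columns `x`, `t`, `p`.
#' @export
as.data.frame.lf_grid <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  data.frame(x = rep(x$x, times = length(x$t)),
             t = rep(x$t, each = length(x$x)),
             p = as.vector(x$p))
}

#' @export
print.lf_grid <- function(x, ...) {
  cat(sprintf("Evidence-density grid: %d x-nodes on [0, %.3g], %d times on [0, %.3g]\n",
              length(x$x), max(x$x), length(x$t), max(x$t)))
  cat(sprintf("  final survival: %.4f\n", survival(x)[length(x$t)]))
  invisible(x)
}

#' Survival probability of the decision process
#'
#' \eqn{S(t) = \int_0^a p(x, t)\,dx} by the composite trapezoid rule over a
#' solved density grid: the probability that the accumulator has not yet
#' been absorbed at either boundary by time t.
#'
#' @param grid An `"lf_grid"` from [fpde_solve()].
#' @return Vector of survival probabilities at the grid times; `S(0) = 1`,
#'   non-increasing, within \[0, 1\].
#' @export
survival <- function(grid) {
  stopifnot(inherits(grid, "lf_grid"))
  w <- rep(grid$h, length(grid$x)); w[c(1, length(w))] <- grid$h / 2
  pmin(pmax(as.numeric(crossprod(grid$p, w)), 0), 1)
}

#' Defective first-passage-time densities from the fractional solver
#'
#' Runs [fpde_solve()] and returns the upper/lower exit densities, i.e. the
#' choice-conditional (defective) decision-time densities the likelihood
#' needs.  Exit mass is attributed to the side of the domain through which
#' the fractional operator (or the drift outflow) removes it.  Between-trial
#' drift and start-point variability, when present in `params`, are handled
#' by Gauss-Legendre mixture quadrature (`n_quad` nodes per varying
#' parameter); the fractional equation itself describes a single-trial
#' process.
#'
#' @inheritParams fpde_solve
#' @param n_quad Quadrature nodes per varying parameter.
#' @return List with `t`, `g_upper`, `g_lower`, `S` (survival at `t`).
#' @export
fpde_fpt <- function(params, nx = 200, nt = 800, T = 3, n_quad = 5L) {
  params <- as_lf_params(params)
  vs <- quad_normal(params$v, params$sv, n_quad)
  zrs <- quad_uniform(params$zr, params$szr, n_quad)
  g_up <- g_lo <- S <- 0
  tt <- NULL
  for (iv in seq_len(nrow(vs))) {
    for (iz in seq_len(nrow(zrs))) {
      p1 <- params; p1$v <- vs[iv, 1]; p1$zr <- zrs[iz, 1]
      p1$sv <- p1$szr <- 0
      g <- fpde_solve(p1, nx = nx, nt = nt, T = T)
      w <- vs[iv, 2] * zrs[iz, 2]
      g_up <- g_up + w * g$g_upper
      g_lo <- g_lo + w * g$g_lower
      S <- S + w * survival(g)
      tt <- g$t
    }
  }
  list(t = tt, g_upper = g_up, g_lower = g_lo, S = S)
}

# mixing-distribution quadrature: (nodes, weights) matrices; point mass when
# the spread parameter is zero
quad_normal <- function(mean, sd, n) {
  if (sd <= 0) return(cbind(mean, 1))
  gl <- gauss_legendre(n, mean - 3 * sd, mean + 3 * sd)
  w <- gl$w * dnorm(gl$x, mean, sd)
  cbind(gl$x, w / sum(w))
}

quad_uniform <- function(mid, range, n) {
  if (range <= 0) return(cbind(mid, 1))
  gl <- gauss_legendre(n, mid - range / 2, mid + range / 2)
  cbind(gl$x, gl$w / sum(gl$w))
}

# Gauss-Legendre nodes/weights on [lo, hi] via the Golub-Welsch eigenproblem
gauss_legendre <- function(n, lo = -1, hi = 1) {
  if (n == 1L) return(list(x = (lo + hi) / 2, w = hi - lo))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b; J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- 2 * rev(e$vectors[1, ]^2)
  list(x = (hi - lo) / 2 * x + (hi + lo) / 2, w = (hi - lo) / 2 * w)
}
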