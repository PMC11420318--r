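# Independent numerical oracles, kept deliberately separate from the package
# implementations they are used to check.

# CDF of the standard symmetric alpha-stable law by direct Simpson-rule
# inversion of the characteristic function exp(-(gamma k)^alpha):
#   F(x) = 1/2 + (1/pi) int_0^inf sin(kx)/k exp(-(gamma k)^alpha) dk
oracle_stable_cdf <- function(x, alpha, gam = 1 / sqrt(2)) {
  kmax <- 45^(1 / alpha) / gam
  k <- seq(1e-9, kmax, length.out = 40001)
  wts <- rep(c(4, 2), length.out = length(k)); wts[1] <- wts[length(k)] <- 1
  h3 <- (k[2] - k[1]) / 3
  vapply(x, function(xi) {
    f <- sin(k * xi) / k * exp(-(gam * k)^alpha)
    0.5 + sum(wts * f) * h3 / pi
  }, numeric(1))
}

# Wiener absorption probability, upper boundary, unit diffusion
oracle_wiener_p_upper <- function(v, a, zr) {
  z <- zr * a
  (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a))
}

# Monte-Carlo survival curve from simulated trials (censored trials are
# still surviving at every t below the cutoff)
mc_survival <- function(sim, t) {
  vapply(t, function(ti) {
    mean(is.na(sim$decision_time) | sim$decision_time > ti)
  }, numeric(1))
}
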