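# Random parameter and state draws used by the property-style tests.
# Rates are drawn small enough that every compartment's outflow stays a
# valid per-step probability, so the same draws serve Euler, adaptive and
# network checks.

random_params <- function() {
  sedpnr_params(
    alpha = runif(1, 0, 0.9),
    beta1 = runif(1, 0.01, 0.2), beta2 = runif(1, 0.01, 0.2),
    beta3 = runif(1, 0.01, 0.2), beta4 = runif(1, 0.01, 0.2),
    gamma = runif(1, 0.01, 0.2),
    lambda1 = runif(1, 0.01, 0.9), lambda2 = runif(1, 0.01, 0.9),
    mu1 = runif(1, 0, 0.2), mu2 = runif(1, 0, 0.2))
}

random_state <- function(scale = 1000) {
  x <- runif(6, 0, scale)
  sedpnr_state(s = x[1], e = x[2], d = x[3], p = x[4], n = x[5], r = x[6])
}

# finite-difference Jacobian of sedpnr_rhs (central differences)
fd_jacobian <- function(params, at = rep(100, 6), h = 1e-4) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    up <- at; up[j] <- up[j] + h
    dn <- at; dn[j] <- dn[j] - h
    names(up) <- names(dn) <- c("s", "e", "d", "p", "n", "r")
    J[, j] <- (sedpnr_rhs(up, params) - sedpnr_rhs(dn, params)) / (2 * h)
  }
  J
}

# exact draws from a discrete power law (zeta distribution), inverse-CDF
rzeta <- function(n, exponent, kmax = 2e5) {
  k <- seq_len(kmax)
  cdf <- cumsum(k^(-exponent))
  cdf <- cdf / cdf[kmax]
  findInterval(runif(n), cdf) + 1L
}
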