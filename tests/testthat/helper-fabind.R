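# Shared fixtures and independent oracles for the test suite.

ref_probe <- function(kd_nM = NULL) {
  probe_params(rf = 0.016, rb = 0.245, R = 3.1, kd_nM = kd_nM)
}

# Independent equilibrium oracle: damped fixed-point iteration on the
# free-site concentration.  The map
#   x <- (s * x + f(x)) / (1 + s),  f(x) = T - P x/(Kp+x) - L x/(Kl+x),
# with damping s set to the local slope bound of f, is a contraction on
# [0, T] and shares no code with the package's bisection solver.
fp_sites_free <- function(T_, P, Kp, L = 0, Kl = 1,
                          tol = 1e-13, max_iter = 100000L) {
  n <- max(length(T_), length(P), length(Kp), length(L), length(Kl))
  T_ <- rep_len(T_, n); P <- rep_len(P, n); Kp <- rep_len(Kp, n)
  L <- rep_len(L, n); Kl <- rep_len(Kl, n)
  x <- T_ / 2
  for (i in seq_len(max_iter)) {
    f <- T_ - P * x / (Kp + x) - L * x / (Kl + x)
    s <- P * Kp / (Kp + x)^2 + L * Kl / (Kl + x)^2
    x_new <- pmin(pmax((s * x + f) / (1 + s), 0), T_)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# sample skewness
skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
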