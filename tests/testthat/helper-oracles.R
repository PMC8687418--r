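# Independent oracles used across the suite.  These are deliberately naive
# (closed forms, brute force, finite differences) and never share code with
# the implementation paths they check.

# Exact conditional mean/variance of the immigration-death count after dt,
# from the analytic law: Binomial(n0, p) survivors + Poisson immigrants,
# p = exp(-theta2 dt), lambda = theta1/theta2 (1 - p).
id_exact_moments <- function(n0, theta, dt) {
  p <- exp(-theta[2] * dt)
  lam <- if (theta[2] > 0) theta[1] / theta[2] * (1 - p) else theta[1] * dt
  list(mean = n0 * p + lam,
       var = n0 * p * (1 - p) + lam)
}

# Central-difference Jacobian of the drift S v
numeric_jacobian <- function(net, x, theta, h = 1e-5) {
  D <- length(x)
  J <- matrix(0, D, D)
  for (j in seq_len(D)) {
    e <- numeric(D); e[j] <- h
    J[, j] <- (ode_rhs(net, x + e, theta) - ode_rhs(net, x - e, theta)) /
      (2 * h)
  }
  J
}

# Brute-force multivariate normal log density (explicit inverse/determinant)
naive_dmvnorm_log <- function(x, mu, Sigma) {
  d <- length(x)
  -0.5 * d * log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * drop(t(x - mu) %*% solve(Sigma) %*% (x - mu))
}

# The three benchmark models' deterministic right-hand sides, written from
# their printed rate equations (not via the stoichiometric machinery)
rhs_id <- function(x, th) th[1] - th[2] * x

rhs_lv <- function(y, th) c(th[1] * y[1] - th[2] * y[1] * y[2],
                            th[2] * y[1] * y[2] - th[3] * y[2])

# reduced state (DNA, P2, mRNA, P), DNA.P2 = dna_t - DNA
rhs_autoreg <- function(x, th, dna_t) {
  dna <- x[1]; p2 <- x[2]; mrna <- x[3]; pp <- x[4]
  dnap2 <- dna_t - dna
  c(-th[1] * dna * p2 + th[2] * dnap2,
    -th[1] * dna * p2 + th[2] * dnap2 + th[5] * pp^2 - th[6] * p2,
    th[3] * dna - th[4] * mrna,
    -2 * th[5] * pp^2 + 2 * th[6] * p2 + th[7] * mrna - th[8] * pp)
}

id_net <- immigration_death_network()
lv_net <- lotka_volterra_network()
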