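th_id <- c(0.6, 0.03)

test_that("residuals vanish when every datum sits on the interval mean", {
  # build a series whose points are the successive rounded-free ODE means
  x <- 30
  states <- numeric(11); states[1] <- x
  for (i in 1:10) {
    x <- unname(lna_moments(id_net, x, th_id, 2)$mean)
    states[i + 1] <- x
  }
  ts <- mss_timeseries(seq(0, 20, 2), matrix(states, ncol = 1),
                       species = "X")
  r <- approximation_residuals(ts, id_net, th_id)
  expect_equal(nrow(r), 10)
  expect_lt(max(abs(r)), 1e-4)
})

test_that("residual count is one less than the measurement count", {
  ts <- ssa_simulate(id_net, 20, seq(0, 40, 2), th_id, seed = 41)
  r <- approximation_residuals(ts, id_net, th_id)
  expect_equal(dim(unclass(r)), c(20L, 1L))
})

test_that("standardised residuals are scale-equivariant", {
  # scaling the covariance by c^2 and the deviation by c leaves r unchanged
  isq <- mssinfer:::.inv_sqrt
  set.seed(5)
  A <- matrix(rnorm(9), 3); Sig <- crossprod(A) + diag(0.2, 3)
  dev <- rnorm(3)
  r1 <- isq(Sig) %*% dev
  r2 <- isq(9 * Sig) %*% (3 * dev)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("the KS check is calibrated and rejects clear alternatives", {
  set.seed(6)
  passes <- vapply(1:50, function(i) {
    r <- structure(matrix(rnorm(100), 100, 1, dimnames = list(NULL, "X")),
                   class = c("mss_residuals", "matrix"))
    normality_check(r, level = 0.01)$pass
  }, logical(1))
  expect_gte(sum(passes), 45)
  degenerate <- structure(matrix(0, 50, 1), class = c("mss_residuals", "matrix"))
  expect_false(normality_check(degenerate)$pass)
  shifted <- structure(matrix(rnorm(50, 2), 50, 1),
                       class = c("mss_residuals", "matrix"))
  expect_false(normality_check(shifted)$pass)
})

test_that("the exact transition pmf has the right special cases", {
  # no immigration: pure-death thinning
  pmf <- id_transition_pmf(10, c(0, 0.1), 3)
  p <- exp(-0.3)
  expect_equal(pmf$prob[pmf$count <= 10], dbinom(0:10, 10, p),
               tolerance = 1e-12)
  # long horizon: stationary Poisson regardless of the start
  th <- c(0.6, 0.03)
  pmf_long <- id_transition_pmf(37, th, 50 / th[2])
  tv <- 0.5 * sum(abs(pmf_long$prob - dpois(pmf_long$count, 20)))
  expect_lt(tv, 1e-8)
  # total mass within truncation
  expect_lt(abs(sum(pmf$prob) - 1), 1e-10)
  expect_lt(abs(sum(id_transition_pmf(20, th, 2)$prob) - 1), 1e-10)
})

test_that("the exact pmf moments equal the LNA moments for linear hazards", {
  for (n0 in c(3, 20)) for (dt in c(1, 5)) {
    pmf <- id_transition_pmf(n0, th_id, dt)
    mu <- sum(pmf$count * pmf$prob)
    v <- sum((pmf$count - mu)^2 * pmf$prob)
    m <- lna_moments(id_net, n0, th_id, dt)
    expect_equal(unname(m$mean), mu, tolerance = 1e-8)
    expect_equal(drop(m$cov), v, tolerance = 1e-7)
  }
})

test_that("the exact pmf matches an SSA histogram within sampling error", {
  n_rep <- 2000
  finals <- vapply(seq_len(n_rep), function(i)
    ssa_simulate(id_net, 20, c(0, 2), th_id, seed = 70000 + i)$states[2, 1],
    numeric(1))
  pmf <- id_transition_pmf(20, th_id, 2)
  # compare cell frequencies on pooled bins with >= 20 expected counts
  br <- c(-0.5, seq(14.5, 24.5, 2), Inf)
  obs <- table(cut(finals, br))
  expp <- vapply(seq_len(length(br) - 1), function(b)
    sum(pmf$prob[pmf$count > br[b] & pmf$count < br[b + 1]]), numeric(1))
  chi2 <- sum((obs - n_rep * expp)^2 / (n_rep * expp))
  expect_lt(chi2, qchisq(0.999, df = length(obs) - 1))
})

test_that("the exact likelihood handles single-interval edge cases", {
  # one molecule, no immigration, death probability one half
  dt <- log(2) / 0.1
  ts <- mss_timeseries(c(0, dt), matrix(c(1, 0), 2, 1), species = "X")
  expect_equal(id_loglik(ts, c(1e-300, 0.1)), log(0.5), tolerance = 1e-9)
})

test_that("the exact estimator recovers parameters from one series", {
  ts <- ssa_simulate(id_net, 10, seq(0, 1000, 10), c(0.6, 0.06), seed = 55)
  f <- id_mle(ts, theta_init = c(1, 0.1))
  expect_true(f$converged)
  expect_lt(max(abs(f$theta - c(0.6, 0.06)) / c(0.6, 0.06)), 0.6)
  # the exact likelihood at the estimate beats the truth
  expect_gte(id_loglik(ts, f$theta), id_loglik(ts, c(0.6, 0.06)) - 1e-8)
})
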