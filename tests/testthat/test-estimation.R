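th_id <- c(0.6, 0.03)
th_lv <- c(0.5, 0.0025, 0.3)

test_that("fits are deterministic and improve on their starting values", {
  ts <- ssa_simulate(id_net, 20, seq(0, 200, 2), th_id, seed = 21)
  f1 <- mss_fit(ts, id_net, theta_init = c(1, 0.1))
  f2 <- mss_fit(ts, id_net, theta_init = c(1, 0.1))
  expect_identical(f1$theta, f2$theta)
  expect_lte(f1$value, f1$init_value)
  expect_true(f1$converged)
  expect_equal(unname(coef(f1)), unname(f1$theta))
  expect_equal(as.numeric(logLik(f1)), -f1$value)
})

test_that("estimates stuck on the acceptance box are classified as divergent", {
  ts <- ssa_simulate(id_net, 20, seq(0, 200, 2), th_id, seed = 22)
  # the optimum for theta1 (~0.6) lies outside a box capped at 0.2
  f <- mss_fit(ts, id_net, theta_init = c(0.1, 0.05),
               box = rbind(c(1e-6, 1e-6), c(0.2, 100)))
  expect_false(f$converged)
})

test_that("a fully observed 'partial' fit matches the plain fit", {
  ts <- ssa_simulate(lv_net, c(71, 79), 0:39, th_lv, seed = 23)
  f_full <- mss_fit(ts, lv_net, theta_init = th_lv * 1.3)
  f_part <- mss_fit(ts, lv_net, theta_init = th_lv * 1.3,
                    observed = c("Y1", "Y2"))
  expect_equal(f_part$theta, f_full$theta, tolerance = 1e-6)
})

test_that("estimates are invariant under species reordering", {
  # the same predator-prey system written with the species swapped
  lv_swap <- reaction_network(
    species = c("Y2", "Y1"),
    educts = matrix(c(0, 1, 1, 1, 1, 0), 2, 3),
    products = matrix(c(0, 2, 2, 0, 0, 0), 2, 3),
    name = "Lotka-Volterra (swapped)")
  ts <- ssa_simulate(lv_net, c(71, 79), 0:39, th_lv, seed = 24)
  ts_swap <- mss_timeseries(ts$times, ts$states[, 2:1])
  f1 <- mss_fit(ts, lv_net, theta_init = th_lv * 1.2)
  f2 <- mss_fit(ts_swap, lv_swap, theta_init = th_lv * 1.2)
  expect_equal(unname(f2$theta), unname(f1$theta), tolerance = 1e-6)
})

test_that("partial-observation fits recover parameters and hidden start", {
  ts <- ssa_simulate(lv_net, c(71, 79), 0:39, th_lv, seed = 25)
  f <- mss_fit(ts, lv_net, theta_init = th_lv * c(1.4, 0.8, 1.2),
               observed = "Y1", hidden_init = 79)
  expect_true(f$converged)
  expect_lt(max(abs(f$theta - th_lv) / th_lv), 0.5)
  # basin check: doubled hidden start reaches the same optimum
  f2 <- mss_fit(ts, lv_net, theta_init = th_lv * c(1.4, 0.8, 1.2),
                observed = "Y1", hidden_init = 158)
  expect_equal(unname(f2$theta), unname(f$theta), tolerance = 1e-3)
  expect_equal(f2$hidden0, f$hidden0, tolerance = 1e-2)
})

test_that("replicated immigration-death estimates are nearly unbiased", {
  n_rep <- 50
  t_grid <- seq(0, 1000, 10)
  ests <- t(vapply(seq_len(n_rep), function(i) {
    set.seed(3000 + i)
    ts <- ssa_simulate(id_net, 20, t_grid, th_id)
    init <- th_id * runif(2, 0.5, 2)
    unname(mss_fit(ts, id_net, theta_init = init)$theta)
  }, numeric(2)))
  av <- colMeans(ests)
  expect_lt(max(abs(av - th_id) / th_id), 0.15)
})

test_that("the noise standard deviation is estimable jointly with theta", {
  # the gene-network design with 500 observations at dt = 0.1 and sigma = 0.5;
  # a single replicate should recover sigma to well under a factor of two
  ar <- autoreg_network(10)
  tha <- c(0.1, 0.7, 0.35, 0.3, 0.1, 0.9, 0.2, 0.1)
  ts <- ssa_simulate(ar, c(6, 6, 8, 25), seq(0, 49.9, 0.1), tha, seed = 7)
  set.seed(7)
  noisy <- mss_timeseries(ts$times,
                          ts$states + rnorm(length(ts$states), 0, 0.5),
                          species = ts$species)
  f <- mss_fit(noisy, ar, theta_init = tha, estimate_sigma = TRUE,
               sigma_init = 1)
  expect_true(f$converged)
  expect_lt(abs(f$sigma - 0.5) / 0.5, 0.5)
  expect_named(coef(f), c(paste0("theta", 1:8), "sigma"))
  # the dimerisation pair stays accurate even under noise
  expect_lt(max(abs(f$theta[5:6] - tha[5:6]) / tha[5:6]), 0.5)
})

test_that("fit methods expose predictions, residuals and simulations", {
  ts <- ssa_simulate(id_net, 20, seq(0, 100, 2), th_id, seed = 28)
  f <- mss_fit(ts, id_net, theta_init = c(1, 0.1))
  pr <- predict(f)
  expect_equal(nrow(pr), 50)
  expect_true(all(c("time", "mean.X", "sd.X") %in% names(pr)))
  rs <- residuals(f)
  expect_equal(dim(unclass(rs)), c(50L, 1L))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_identical(sim[[1]]$times, ts$times)
  sm <- summary(f)
  expect_s3_class(sm, "summary.mss_fit")
  f_png <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f_png); plot(f); grDevices::dev.off()
  expect_true(file.exists(f_png))
})
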