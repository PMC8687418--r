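test_that("mass-action propensities match direct monomial evaluation", {
  expect_equal(propensities(id_net, 10, c(0.6, 0.03)), c(0.6, 0.3))
  expect_equal(propensities(lv_net, c(71, 79), c(0.5, 0.0025, 0.3)),
               c(35.5, 14.0225, 23.7))
  # zero state annihilates every hazard with at least one educt
  expect_equal(propensities(lv_net, c(0, 0), c(0.5, 0.0025, 0.3)),
               c(0, 0, 0))
  ar <- autoreg_network(10)
  th <- c(0.1, 0.7, 0.35, 0.3, 0.1, 0.9, 0.2, 0.1)
  v <- propensities(ar, c(6, 6, 8, 25), th)
  expect_equal(v, c(0.1 * 6 * 6, 0.7 * 4, 0.35 * 6, 0.3 * 8,
                    0.1 * 25^2, 0.9 * 6, 0.2 * 8, 0.1 * 25))
  # combinatorial dimerisation option switches P^2 to P(P-1)/2
  arc <- autoreg_network(10, combinatorial_dimer = TRUE)
  expect_equal(propensities(arc, c(6, 6, 8, 25), th)[5], 0.1 * 25 * 24 / 2)
})

test_that("invalid states and parameter vectors are rejected", {
  expect_error(propensities(id_net, -1, c(0.6, 0.03)), "non-negative")
  expect_error(propensities(id_net, 10, c(0.6, 0.03, 1)), "2 components")
  expect_error(autoreg_network(0), "positive")
})

test_that("stoichiometry is the product-educt difference for all builtins", {
  for (net in list(id_net, lv_net, autoreg_network(2), autoreg_network(10)))
    expect_equal(net$S, net$u - net$q, ignore_attr = TRUE)
  expect_equal(unname(id_net$S), matrix(c(1, -1), 1, 2))
  expect_equal(unname(lv_net$S), matrix(c(1, 0, -1, 1, 0, -1), 2, 3))
  # reaction 1 of the reduced auto-regulatory model: DNA + P2 -> DNA.P2
  expect_equal(unname(autoreg_network(10)$S[, 1]), c(-1, -1, 0, 0))
})

test_that("drift equals the printed rate equations on random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    x <- runif(1, 0, 60); th <- runif(2, 0.01, 2)
    expect_equal(unname(ode_rhs(id_net, x, th)), rhs_id(x, th),
                 tolerance = 1e-12)
    y <- runif(2, 0, 300); th3 <- runif(3, 0.001, 1)
    expect_equal(unname(ode_rhs(lv_net, y, th3)), rhs_lv(y, th3),
                 tolerance = 1e-12)
    dna_t <- sample(c(2, 10), 1)
    xa <- c(runif(1, 0, dna_t), runif(3, 0, 40))
    th8 <- runif(8, 0.01, 1)
    expect_equal(unname(ode_rhs(autoreg_network(dna_t), xa, th8)),
                 rhs_autoreg(xa, th8, dna_t), tolerance = 1e-12)
  }
})

test_that("analytic Jacobian agrees with central differences", {
  # immigration-death: J = -theta2 everywhere
  expect_equal(unname(network_jacobian(id_net, 17, c(0.6, 0.03))),
               matrix(-0.03, 1, 1))
  # Lotka-Volterra at its deterministic equilibrium has zero trace
  th <- c(0.5, 0.0025, 0.3)
  eq <- c(th[3] / th[2], th[1] / th[2])
  expect_equal(eq, c(120, 200))
  expect_equal(sum(diag(network_jacobian(lv_net, eq, th))), 0,
               tolerance = 1e-12)
  set.seed(7)
  nets <- list(id = id_net, lv = lv_net, ar = autoreg_network(10),
               arc = autoreg_network(10, combinatorial_dimer = TRUE))
  for (net in nets) {
    D <- length(net$species)
    for (rep in 1:5) {
      x <- runif(D, 1, 30)
      th <- runif(net$n_par, 0.05, 1)
      expect_lt(max(abs(network_jacobian(net, x, th) -
                          numeric_jacobian(net, x, th))), 1e-6)
    }
  }
})

test_that("diffusion matrix has the stated structure and is PSD", {
  expect_equal(unname(diffusion_matrix(id_net, 20, c(0.6, 0.03))),
               matrix(1.2, 1, 1))
  th <- c(0.5, 0.0025, 0.3)
  v <- propensities(lv_net, c(71, 79), th)
  expect_equal(unname(diffusion_matrix(lv_net, c(71, 79), th)),
               matrix(c(v[1] + v[2], -v[2], -v[2], v[2] + v[3]), 2, 2))
  set.seed(8)
  for (net in list(lv_net, autoreg_network(10))) {
    for (rep in 1:10) {
      x <- runif(length(net$species), 0, 50)
      Dm <- diffusion_matrix(net, x, runif(net$n_par, 0.05, 1))
      expect_equal(Dm, t(Dm))
      expect_gt(min(eigen(Dm, symmetric = TRUE)$values), -1e-12)
    }
  }
})

test_that("network definition files round-trip, and builtins resolve by name", {
  for (ext in c("json", "yaml")) {
    if (ext == "yaml") skip_if_not_installed("yaml")
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    net <- autoreg_network(10, combinatorial_dimer = TRUE)
    write_network(net, f)
    back <- read_network(f)
    th <- runif(8, 0.1, 1); x <- c(3, 6, 8, 25)
    expect_equal(back$S, net$S)
    expect_equal(propensities(back, x, th), propensities(net, x, th))
    expect_equal(network_jacobian(back, x, th), network_jacobian(net, x, th))
  }
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(builtin = "lotka_volterra"), f2,
                       auto_unbox = TRUE)
  expect_equal(read_network(f2)$S, lv_net$S)
  expect_equal(builtin_network("autoreg", dna_total = 2)$eliminated$total, 2)
})
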