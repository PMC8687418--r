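#' Residual-based check of the Gaussian transition approximation
#'
#' @description
#' For each inter-measurement interval the standardised residual
#' \deqn{r_i = \left(\Sigma(\Delta_i)^{obs} + \Sigma_{meas}\right)^{-1/2}
#'       \left(x(\Delta_i; \theta, \tilde\nu_{i-1})^{obs} -
#'       \nu_i^{obs}\right)}
#' is the multivariate-normal "random number" that would have produced the
#' datum under the Gaussian transition approximation; if the approximation
#' holds at `theta`, each residual component series is i.i.d. standard
#' normal.  The inverse square root is the symmetric (eigendecomposition)
#' root, which is covariant under species permutation.  There are \eqn{n}
#' residuals for \eqn{n + 1} measurements.
#'
#' `normality_check()` runs a one-sample Kolmogorov-Smirnov test of each
#' component series against N(0, 1).  A pass supports the approximation; a
#' failure flags it as questionable but does not preclude useful estimates
#' (the covariance acts as a weighting factor only), so the check is best
#' read as supportive rather than as a strict rejection rule.
#'
#' @inheritParams mss_objective
#' @return `approximation_residuals()`: an object of class
#'   `"mss_residuals"` — an \eqn{n \times d} matrix of standardised
#'   residuals with the observed species as columns.
#' @export
approximation_residuals <- function(ts, network, theta, observed = NULL,
                                    nu0_hid = NULL, sigma_meas = NULL,
                                    rtol = 1e-8, atol = 1e-10,
                                    method = "lsoda") {
  theta <- .check_theta(network, theta)
  obs_idx <- .resolve_observed(network, ts, observed)
  d <- length(obs_idx)
  data <- .observed_data(network, ts, obs_idx)
  n <- length(ts$times) - 1L
  Sm <- .resolve_sigma_meas(sigma_meas, d)
  path <- .shooting_path(network, ts$times, data, theta, obs_idx,
                         nu0_hid = nu0_hid, with_cov = TRUE,
                         rtol = rtol, atol = atol, method = method)
  r <- matrix(0, n, d, dimnames = list(NULL, network$species[obs_idx]))
  for (i in seq_len(n)) {
    Sig <- .regularise_cov(path$cov[obs_idx, obs_idx, i, drop = TRUE])
    if (d == 1L) Sig <- matrix(Sig, 1, 1)
    if (!is.null(Sm)) Sig <- Sig + Sm
    isq <- tryCatch(.inv_sqrt(Sig), error = function(e)
      stop(sprintf("singular covariance on interval %d (t = %g to %g)",
                   i, ts$times[i], ts$times[i + 1]), call. = FALSE))
    r[i, ] <- drop(isq %*% (path$mean[i, obs_idx] - data[i + 1, ]))
  }
  structure(r, class = c("mss_residuals", "matrix"))
}

#' @export
print.mss_residuals <- function(x, ...) {
  cat(sprintf("standardised one-step residuals: %d intervals x %d species\n",
              nrow(x), ncol(x)))
  print(summary(unclass(x)))
  invisible(x)
}

#' @rdname approximation_residuals
#' @param r an `"mss_residuals"` matrix.
#' @param level significance level for the per-component KS test.
#' @return `normality_check()`: a data frame with one row per observed
#'   species (sample mean and variance, KS statistic, p-value, pass flag).
#' @export
normality_check <- function(r, level = 0.01) {
  r <- unclass(r)
  if (nrow(r) < 5) stop("too few residuals for a meaningful check")
  out <- data.frame(species = colnames(r) %||% paste0("X", seq_len(ncol(r))),
                    mean = colMeans(r), var = apply(r, 2, stats::var),
                    ks_stat = NA_real_, p_value = NA_real_, pass = NA)
  for (j in seq_len(ncol(r))) {
    kt <- suppressWarnings(stats::ks.test(r[, j], "pnorm"))
    out$ks_stat[j] <- unname(kt$statistic)
    out$p_value[j] <- kt$p.value
    out$pass[j] <- kt$p.value >= level
  }
  rownames(out) <- NULL
  out
}

#' Exact transition law of the immigration-death process
#'
#' @description
#' The immigration-death model is one of the few reaction networks whose
#' master equation is solvable in closed form: starting from \eqn{n_0}
#' molecules, the count after time \eqn{\Delta t} is the independent sum of
#' the surviving initial molecules, Binomial\eqn{(n_0, e^{-\theta_2 \Delta
#' t})}, and the accumulated immigrants, Poisson with mean
#' \eqn{\theta_1/\theta_2 (1 - e^{-\theta_2 \Delta t})} (pure immigration
#' \eqn{\theta_1 \Delta t} when \eqn{\theta_2 = 0}).  This law serves both
#' as an independent oracle for the LNA moments (for linear hazards the LNA
#' mean and variance are exact) and as the reference "exact method"
#' estimator.
#'
#' @param n0 non-negative integer initial count.
#' @param theta parameters \eqn{(\theta_1, \theta_2)}, both \eqn{\ge 0}.
#' @param dt time span.
#' @param tail_mass pmf truncation: the returned support covers all but less
#'   than this much probability.
#' @return `id_transition_pmf()`: a data frame with columns `count` and
#'   `prob`.
#' @export
id_transition_pmf <- function(n0, theta, dt, tail_mass = 1e-12) {
  stopifnot(n0 >= 0, n0 == round(n0), length(theta) == 2,
            all(theta >= 0), dt >= 0)
  p <- exp(-theta[2] * dt)
  lam <- if (theta[2] > 0) theta[1] / theta[2] * (1 - p) else theta[1] * dt
  hi <- n0 + if (lam > 0) stats::qpois(tail_mass / 2, lam,
                                       lower.tail = FALSE) else 0
  counts <- 0:hi
  probs <- vapply(counts, .id_pmf_point, numeric(1),
                  n0 = n0, p = p, lam = lam)
  data.frame(count = counts, prob = probs)
}

## P(X = nu) for X = Binomial(n0, p) + Poisson(lam), by direct convolution
.id_pmf_point <- function(nu, n0, p, lam) {
  j <- 0:min(n0, nu)
  if (lam == 0)
    return(if (nu <= n0) stats::dbinom(nu, n0, p) else 0)
  sum(stats::dbinom(j, n0, p) * stats::dpois(nu - j, lam))
}

#' @rdname id_transition_pmf
#' @param ts a one-species immigration-death [mss_timeseries()].
#' @return `id_loglik()`: the exact log-likelihood of the series (sum of log
#'   transition probabilities).
#' @export
id_loglik <- function(ts, theta) {
  stopifnot(ncol(ts$states) == 1)
  x <- as.numeric(ts$states[, 1])
  n <- length(x) - 1L
  ll <- 0
  for (i in seq_len(n)) {
    dt <- ts$times[i + 1] - ts$times[i]
    p <- exp(-theta[2] * dt)
    lam <- if (theta[2] > 0) theta[1] / theta[2] * (1 - p) else theta[1] * dt
    pr <- .id_pmf_point(x[i + 1], x[i], p, lam)
    if (pr <= 0) return(-Inf)
    ll <- ll + log(pr)
  }
  ll
}

#' @rdname id_transition_pmf
#' @param theta_init positive starting values for the maximisation.
#' @param box parameter box as in [mss_fit()].
#' @param control passed to [stats::optim()].
#' @return `id_mle()`: an `"mss_fit"`-classed object (variant
#'   `"exact_id"`) holding the exact maximum-likelihood estimate.
#' @export
id_mle <- function(ts, theta_init = c(1, 0.1), box = c(1e-6, 100),
                   control = list()) {
  net <- immigration_death_network()
  box <- .resolve_box(box, 2L)
  n_evals <- 0L
  fn <- function(par) {
    n_evals <<- n_evals + 1L
    val <- -id_loglik(ts, exp(par))
    if (!is.finite(val)) 1e10 else val
  }
  par0 <- log(theta_init)
  f0 <- fn(par0)
  if (f0 >= 1e10)
    stop("exact likelihood is not finite at the starting values")
  ctrl <- utils::modifyList(list(maxit = 300L, reltol = 1e-10), control)
  opt <- stats::optim(par0, fn, method = "BFGS", control = ctrl)
  theta_hat <- stats::setNames(exp(opt$par), net$theta_names)
  inside <- all(theta_hat > box[1, ] * (1 + 1e-6)) &&
            all(theta_hat < box[2, ] * (1 - 1e-6))
  structure(list(theta = theta_hat, hidden0 = NULL, sigma = NULL,
                 value = opt$value,
                 converged = opt$convergence == 0L && inside,
                 convergence = opt$convergence, message = opt$message,
                 counts = c(opt$counts, total = n_evals),
                 init_value = f0, theta_init = theta_init,
                 objective = NULL, obs_idx = 1L, hid_idx = integer(0),
                 variant = "exact_id", box = box, network = net, ts = ts,
                 call = match.call()),
            class = "mss_fit")
}
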