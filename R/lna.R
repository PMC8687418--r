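#' @useDynLib mssinfer, .registration = TRUE
NULL

.MSS_MAXPAR <- 4096L

## pack the network + parameters into the flat vector read by the compiled
## derivative routine; padded to fixed length (the compiled side copies a
## fixed-size block)
.pack_parms <- function(network, theta, with_cov, nblocks = 1L) {
  D <- length(network$species)
  r <- ncol(network$S)
  ct <- network$complement_totals
  ct[is.na(ct)] <- -1
  p <- c(D, r, network$volume, as.numeric(with_cov), nblocks,
         as.numeric(theta)[network$param_map],
         as.numeric(network$S),
         as.numeric(network$rate_exponents),
         as.numeric(ct),
         as.numeric(network$combinatorial))
  if (length(p) > .MSS_MAXPAR)
    stop("network too large for the compiled moment system")
  c(p, numeric(.MSS_MAXPAR - length(p)))
}

.ncov <- function(D) D * (D + 1L) / 2L

## evaluate an expression with console output diverted: the Fortran solvers
## print step-size diagnostics directly to the console when an integration
## fails, which floods logs during optimisation (failures there are expected
## and handled by the penalty mechanism)
.quietly <- function(expr) {
  con <- file(nullfile(), open = "w")
  sink(con)
  on.exit({ sink(); close(con) })
  expr
}

## upper-triangle (column-major, i <= j) <-> full matrix
.tri_to_mat <- function(v, D) {
  m <- matrix(0, D, D)
  m[upper.tri(m, diag = TRUE)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Interval-wise transition moments (ODE mean and LNA covariance)
#'
#' Jointly integrates the \eqn{D} mean equations \eqn{dx/dt = S v(x,\theta)}
#' and the \eqn{D(D+1)/2} distinct covariance equations
#' \deqn{d\Sigma/dt = J \Sigma + \Sigma J^\top + \Omega^{-1} D(x(t), \theta),
#'       \qquad \Sigma(0) = 0,}
#' with the Jacobian \eqn{J} and diffusion matrix \eqn{D} evaluated along the
#' evolving mean \eqn{x(t)}, from the state `x0` over a time span `dt`.
#' These are the mean and covariance of the Gaussian transition approximation
#' for one inter-measurement interval.
#'
#' @param network a [reaction_network()].
#' @param x0 non-negative state at the start of the interval.
#' @param theta positive kinetic parameters.
#' @param dt interval length (\eqn{\ge 0}).
#' @param rtol,atol integrator tolerances.
#' @param method a [deSolve::ode()] method; the default `"lsoda"` switches
#'   automatically between stiff and non-stiff regimes.
#' @return A list with elements `mean` (length-\eqn{D} vector) and `cov`
#'   (\eqn{D \times D} symmetric matrix), class `"mss_moments"`.
#' @export
lna_moments <- function(network, x0, theta, dt, rtol = 1e-8, atol = 1e-10,
                        method = "lsoda") {
  x0 <- .check_state(network, x0)
  theta <- .check_theta(network, theta)
  if (dt < 0) stop("'dt' must be non-negative")
  D <- length(x0)
  if (dt == 0) {
    return(structure(list(mean = stats::setNames(x0, network$species),
                          cov = matrix(0, D, D)), class = "mss_moments"))
  }
  y0 <- c(x0, numeric(.ncov(D)))
  out <- deSolve::ode(y = y0, times = c(0, dt), func = "mssnet_deriv",
                      parms = .pack_parms(network, theta, TRUE),
                      dllname = "mssinfer", initfunc = "mssnet_init",
                      rtol = rtol, atol = atol, method = method)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out[nrow(out), -1])))
    stop("moment integration failed (stiffness or blow-up); ",
         "partial state: ", paste(signif(out[nrow(out), -1], 4),
                                  collapse = ", "))
  fin <- out[nrow(out), -1]
  Sig <- .tri_to_mat(fin[(D + 1):(D + .ncov(D))], D)
  if (max(abs(Sig - t(Sig))) > 1e-10)
    stop("covariance lost symmetry during integration")
  structure(list(mean = stats::setNames(fin[1:D], network$species),
                 cov = (Sig + t(Sig)) / 2),
            class = "mss_moments")
}

#' @export
print.mss_moments <- function(x, ...) {
  cat("transition moments\nmean:\n")
  print(x$mean)
  cat("covariance:\n")
  print(x$cov)
  invisible(x)
}

## Integrate the full multiple-shooting moment path for a time series in a
## single deSolve call: at every interior measurement time the observed state
## components are reset to the datum and the covariance block to zero (the
## shooting re-initialisation), implemented through deSolve's event mechanism.
## Hidden components are left untouched, i.e. they carry the interval-wise ODE
## propagation.  Pre-reset moments are read just before each event via dense
## output at t_i - eps.
##
## Returns per-interval means (n x D), covariance array (D x D x n, NULL if
## with_cov = FALSE) and the hidden-state path.
.shooting_path <- function(network, times, data, theta, obs_idx,
                           nu0_hid = NULL, with_cov = TRUE,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  D <- length(network$species)
  n <- length(times) - 1L
  nc <- if (with_cov) .ncov(D) else 0L
  hid_idx <- setdiff(seq_len(D), obs_idx)

  ## fully observed series on an equidistant grid: all shooting intervals are
  ## independent, so integrate them as stacked blocks in one solver call
  dts <- diff(times)
  if (length(hid_idx) == 0L && n >= 1L &&
      diff(range(dts)) <= 1e-9 * max(dts))
    return(.shooting_path_batch(network, n, dts[1], data, theta,
                                with_cov, rtol, atol))

  x0 <- numeric(D)
  x0[obs_idx] <- data[1, ]
  if (length(hid_idx)) {
    if (is.null(nu0_hid) || length(nu0_hid) != length(hid_idx))
      stop("initial values for the hidden species are required")
    x0[hid_idx] <- nu0_hid
  }
  y0 <- c(x0, numeric(nc))
  names(y0) <- c(paste0("x", seq_len(D)), if (nc) paste0("s", seq_len(nc)))

  eps <- 1e-6 * min(diff(times))
  t_pre <- times[-1] - eps
  t_evt <- times[2:n]                     # resets for intervals 2..n
  if (n == 1L) t_evt <- numeric(0)
  times_ode <- sort(unique(c(times[1], t_pre, t_evt, times[n + 1])))

  events <- NULL
  if (length(t_evt)) {
    var_idx <- names(y0)[c(obs_idx, if (nc) D + seq_len(nc))]
    events <- data.frame(
      var = rep(var_idx, times = length(t_evt)),
      time = rep(t_evt, each = length(var_idx)),
      value = as.numeric(vapply(seq_along(t_evt), function(i)
        c(data[i + 1, ], numeric(nc)), numeric(length(var_idx)))),
      method = "rep")
  }

  out <- .quietly(deSolve::ode(y = y0, times = times_ode, func = "mssnet_deriv",
                      parms = .pack_parms(network, theta, with_cov),
                      dllname = "mssinfer", initfunc = "mssnet_init",
                      rtol = rtol, atol = atol, method = method,
                      events = if (!is.null(events)) list(data = events),
                      maxsteps = 1000))
  if (attr(out, "istate")[1] < 0)
    stop("moment integration failed over the observation horizon")
  rows <- match(round(t_pre, 12), round(out[, 1], 12))
  vals <- out[rows, -1, drop = FALSE]
  if (any(!is.finite(vals)))
    stop("non-finite moments in the shooting path")
  mean_path <- vals[, seq_len(D), drop = FALSE]
  colnames(mean_path) <- network$species
  cov_path <- NULL
  if (with_cov) {
    cov_path <- array(apply(vals[, D + seq_len(nc), drop = FALSE], 1,
                            .tri_to_mat, D = D),
                      dim = c(D, D, n))
  }
  list(mean = mean_path, cov = cov_path,
       hidden = mean_path[, hid_idx, drop = FALSE], hid_idx = hid_idx)
}

## stacked-block integration of n independent shooting intervals over one
## common span dt; block i starts at datum i with zero covariance.  The
## non-stiff Adams method avoids the (dense) Jacobian of the stacked system.
.shooting_path_batch <- function(network, n, dt, data, theta, with_cov,
                                 rtol, atol) {
  D <- length(network$species)
  nc <- if (with_cov) .ncov(D) else 0L
  bs <- D + nc
  y0 <- numeric(n * bs)
  for (i in seq_len(n))
    y0[(i - 1L) * bs + seq_len(D)] <- data[i, ]
  out <- .quietly(deSolve::ode(y = y0, times = c(0, dt), func = "mssnet_deriv",
                      parms = .pack_parms(network, theta, with_cov,
                                          nblocks = n),
                      dllname = "mssinfer", initfunc = "mssnet_init",
                      rtol = rtol, atol = atol, method = "adams",
                      maxsteps = 500))
  if (attr(out, "istate")[1] < 0 || nrow(out) < 2)
    stop("moment integration failed over the observation horizon")
  fin <- out[nrow(out), -1]
  if (any(!is.finite(fin)))
    stop("non-finite moments in the shooting path")
  blocks <- matrix(fin, nrow = bs)
  mean_path <- t(blocks[seq_len(D), , drop = FALSE])
  colnames(mean_path) <- network$species
  cov_path <- NULL
  if (with_cov)
    cov_path <- array(apply(blocks[D + seq_len(nc), , drop = FALSE], 2,
                            .tri_to_mat, D = D),
                      dim = c(D, D, n))
  list(mean = mean_path, cov = cov_path,
       hidden = mean_path[, integer(0), drop = FALSE],
       hid_idx = integer(0))
}

## symmetrise + jitter regularisation for a covariance block; the floor also
## covers the exactly singular case of die-out intervals, where all hazards
## (and hence the LNA covariance) vanish and the transition is deterministic
.regularise_cov <- function(Sig, jitter_scale = 1e-8) {
  Sig <- (Sig + t(Sig)) / 2
  scale <- max(1, sum(diag(Sig)) / nrow(Sig))
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < jitter_scale * scale)
    Sig <- Sig + diag(jitter_scale * scale, nrow(Sig))
  Sig
}

## log density of N(mu, Sigma) at x via Cholesky
.dmvnorm_log <- function(x, mu, Sigma) {
  R <- chol(Sigma)                       # errors if not PD
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

## symmetric inverse square root (eigendecomposition), permutation-covariant
.inv_sqrt <- function(Sigma, tol = 1e-12) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam <= tol * max(abs(lam), 1)))
    stop("covariance is numerically singular")
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

#' Gaussian transition log-density
#'
#' Log of the multivariate normal transition density with mean
#' `m$mean[obs_idx]` and covariance `m$cov[obs_idx, obs_idx] + sigma_meas`,
#' evaluated at the observed components of the next datum.  Computed through
#' a Cholesky factorisation; the covariance block is symmetrised and, if its
#' smallest eigenvalue is negative, regularised with a trace-scaled jitter.
#'
#' @param m transition moments from [lna_moments()].
#' @param nu_next the next measurement (full state vector, or already
#'   restricted to `obs_idx`).
#' @param obs_idx indices of the observed species (default: all).
#' @param sigma_meas measurement-noise covariance (`NULL` or a matrix of the
#'   observed dimension).
#' @return The log transition density (a scalar).
#' @export
transition_logpdf <- function(m, nu_next, obs_idx = NULL, sigma_meas = NULL) {
  D <- length(m$mean)
  if (is.null(obs_idx)) obs_idx <- seq_len(D)
  Sig <- .regularise_cov(m$cov[obs_idx, obs_idx, drop = FALSE])
  if (!is.null(sigma_meas)) {
    sigma_meas <- as.matrix(sigma_meas)
    if (max(abs(sigma_meas - t(sigma_meas))) > 1e-10 ||
        min(eigen(sigma_meas, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-10)
      stop("'sigma_meas' must be symmetric positive semi-definite")
    Sig <- Sig + sigma_meas
  }
  x <- if (length(nu_next) == D) nu_next[obs_idx] else nu_next
  .dmvnorm_log(as.numeric(x), as.numeric(m$mean[obs_idx]), Sig)
}

#' Approximate trajectory simulation from the Gaussian transition law
#'
#' Iteratively draws \eqn{\nu_i \sim N(\mu_i, \Sigma_i)} with the
#' interval-wise moments of [lna_moments()], rounds to the nearest integer,
#' clamps at zero, and conditions the following interval on the drawn state.
#' This is the fast surrogate for exact simulation implied by the transition
#' approximation; comparing it against [ssa_simulate()] is a quick visual
#' validity check.
#'
#' @inheritParams ssa_simulate
#' @param nu0 integer initial state.
#' @param round round the draws to non-negative integers (the jump-process
#'   convention).  With `round = FALSE` the raw Gaussian draws are returned
#'   (used by the residual diagnostics, which are exact for raw draws).
#' @param sd_scale multiplier on the covariance's scale (standard-deviation
#'   units); `sd_scale = 0` gives the noise-free interval-wise ODE skeleton.
#' @param rtol,atol,method integrator settings, as in [lna_moments()].
#' @return An [mss_timeseries()].
#' @export
lna_simulate <- function(network, nu0, t_grid, theta, seed = NULL,
                         round = TRUE, sd_scale = 1,
                         rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  nu0 <- .check_state(network, nu0)
  theta <- .check_theta(network, theta)
  if (!is.null(seed)) set.seed(seed)
  D <- length(nu0)
  n_grid <- length(t_grid)
  out <- matrix(0, n_grid, D)
  out[1, ] <- nu0
  x <- nu0
  for (i in seq_len(n_grid - 1L)) {
    m <- lna_moments(network, x, theta, t_grid[i + 1] - t_grid[i],
                     rtol = rtol, atol = atol, method = method)
    Sig <- .regularise_cov(m$cov) * sd_scale^2
    e <- eigen(Sig, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    draw <- m$mean + drop(e$vectors %*% (sqrt(lam) * stats::rnorm(D)))
    out[i + 1, ] <- draw
    x <- pmax(if (round) base::round(draw) else draw, 0)
    if (round) out[i + 1, ] <- x
  }
  mss_timeseries(t_grid, out, species = network$species)
}
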