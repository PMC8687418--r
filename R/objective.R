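#' Multiple-shooting negative log-likelihood for stochastic kinetics
#'
#' @description
#' Evaluates the deterministic objective
#' \deqn{F(\nu, \theta) = -\sum_{i=1}^{n} \log \phi\!\left(\nu_i;\;
#'   x(\Delta_i; \theta, \nu_{i-1}),\; \Sigma(\Delta_i; \theta)\right)}
#' where \eqn{\phi} is the multivariate normal density, the mean is the
#' reaction-rate ODE solution over the interval started at the previous
#' datum, and the covariance is the interval-wise LNA solution started at
#' zero.  Every interval is re-initialised at the measured state (the
#' multiple-shooting step), so the objective is a sum of one-step-ahead
#' Gaussian transition scores.
#'
#' With partial observation (`observed` a proper subset of the species), the
#' unobserved components of the shooting start are propagated
#' deterministically from interval to interval (the previous interval's ODE
#' endpoint), the initial hidden state `nu0_hid` is a free input, and the
#' density is evaluated on the observed marginal.  With measurement noise,
#' the observed-block covariance is inflated to
#' \eqn{\Sigma^{obs} + \Sigma_{meas}} and the noisy datum still serves as the
#' shooting re-initialisation (a simple state estimate).
#'
#' `variant = "constant"` replaces the LNA covariance with \eqn{c\, I}
#' (the predecessor constant-variance objective); its minimiser is
#' independent of \eqn{c}, which only shifts the objective by an additive
#' constant relative to the multiple-shooting residual sum of squares.
#'
#' @param ts an [mss_timeseries()] holding the measurements (only the
#'   `observed` columns are used).
#' @param network a [reaction_network()].
#' @param theta positive kinetic parameters.
#' @param observed observed species, as indices or names; default all.
#' @param nu0_hid non-negative initial values for the hidden species
#'   (required when `observed` is a proper subset).
#' @param sigma_meas measurement-noise covariance: `NULL` (noise-free), a
#'   scalar standard deviation \eqn{\sigma} (meaning \eqn{\sigma^2 I}), or a
#'   full \eqn{d \times d} PSD matrix.
#' @param variant `"lna"` (extended objective) or `"constant"`.
#' @param const_var the constant variance \eqn{c > 0} for
#'   `variant = "constant"`.
#' @param rtol,atol,method integrator settings, as in [lna_moments()].
#' @return An object of class `"mss_objective"`: a list with `value` (the
#'   negative log-likelihood), `per_interval` (its \eqn{n} addends),
#'   `hidden_path` (propagated hidden states at \eqn{t_1, \dots, t_n}),
#'   `mean_path`, `cov_path` and the call ingredients.
#' @export
mss_objective <- function(ts, network, theta, observed = NULL,
                          nu0_hid = NULL, sigma_meas = NULL,
                          variant = c("lna", "constant"), const_var = 1,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  variant <- match.arg(variant)
  theta <- .check_theta(network, theta)
  obs_idx <- .resolve_observed(network, ts, observed)
  d <- length(obs_idx)
  data <- .observed_data(network, ts, obs_idx)
  n <- length(ts$times) - 1L
  if (n < 1L) stop("a time series needs at least two measurement points")
  Sm <- .resolve_sigma_meas(sigma_meas, d)
  if (variant == "constant" && const_var <= 0)
    stop("'const_var' must be positive")

  path <- .shooting_path(network, ts$times, data, theta, obs_idx,
                         nu0_hid = nu0_hid, with_cov = variant == "lna",
                         rtol = rtol, atol = atol, method = method)

  per <- numeric(n)
  for (i in seq_len(n)) {
    mu <- path$mean[i, obs_idx]
    dev <- data[i + 1, ] - mu
    if (variant == "lna") {
      Sig <- .regularise_cov(path$cov[obs_idx, obs_idx, i, drop = TRUE])
      if (d == 1L) Sig <- matrix(Sig, 1, 1)
      if (!is.null(Sm)) Sig <- Sig + Sm
      ll <- tryCatch(.dmvnorm_log(data[i + 1, ], mu, Sig),
                     error = function(e)
                       stop(sprintf(
                         "covariance not positive definite on interval %d (t = %g to %g)",
                         i, ts$times[i], ts$times[i + 1]), call. = FALSE))
      per[i] <- -ll
    } else {
      per[i] <- d / 2 * log(2 * pi * const_var) + sum(dev^2) / (2 * const_var)
    }
  }

  structure(list(value = sum(per), per_interval = per,
                 hidden_path = path$hidden, hid_idx = path$hid_idx,
                 mean_path = path$mean, cov_path = path$cov,
                 obs_idx = obs_idx, theta = theta, variant = variant,
                 sigma_meas = Sm, const_var = const_var),
            class = "mss_objective")
}

#' @export
print.mss_objective <- function(x, ...) {
  cat(sprintf("%s multiple-shooting objective: %.6g over %d intervals\n",
              if (x$variant == "lna") "extended (LNA)" else "constant-variance",
              x$value, length(x$per_interval)))
  invisible(x)
}

.resolve_observed <- function(network, ts, observed) {
  D <- length(network$species)
  if (is.null(observed)) return(seq_len(D))
  if (is.character(observed)) {
    idx <- match(observed, network$species)
    if (anyNA(idx)) stop("unknown species in 'observed'")
  } else {
    idx <- as.integer(observed)
    if (any(idx < 1L | idx > D)) stop("'observed' indices out of range")
  }
  if (anyDuplicated(idx)) stop("duplicate entries in 'observed'")
  if (length(idx) == 0L) stop("'observed' must be non-empty")
  idx
}

## measurement matrix restricted to the observed species, by name when the
## series carries labels matching the network
.observed_data <- function(network, ts, obs_idx) {
  st <- ts$states
  want <- network$species[obs_idx]
  if (!is.null(colnames(st)) && all(want %in% colnames(st)))
    return(st[, want, drop = FALSE])
  if (ncol(st) == length(network$species))
    return(st[, obs_idx, drop = FALSE])
  if (ncol(st) == length(obs_idx))
    return(st)
  stop("cannot align the time-series columns with the observed species")
}

.resolve_sigma_meas <- function(sigma_meas, d) {
  if (is.null(sigma_meas)) return(NULL)
  if (is.matrix(sigma_meas)) {
    if (!all(dim(sigma_meas) == d))
      stop(sprintf("'sigma_meas' must be %d x %d", d, d))
    if (max(abs(sigma_meas)) == 0) return(NULL)
    return(sigma_meas)
  }
  if (length(sigma_meas) != 1L || sigma_meas < 0)
    stop("'sigma_meas' must be a matrix or a non-negative scalar sd")
  if (sigma_meas == 0) return(NULL)
  diag(sigma_meas^2, d)
}
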