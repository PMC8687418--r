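#' Define a simulation-study scenario
#'
#' A scenario bundles everything needed to reproduce a replicated
#' generate-then-estimate experiment: the model, the true parameters, the
#' measurement grid, the observation scheme, the estimator variant, the
#' replicate count and the base seed.  Replicate `i` is fully determined by
#' the derived seed `base_seed + i`: the seed drives the exact simulation,
#' the measurement noise, and the starting values for the optimiser (the
#' true parameters perturbed multiplicatively by independent U[0.5, 2]
#' factors).
#'
#' @param model a [reaction_network()] or a built-in model name for
#'   [builtin_network()].
#' @param theta_true true kinetic parameters used to generate the data.
#' @param x0 integer initial state, or `"steady_state"` for the
#'   deterministic steady state (immigration-death: \eqn{\theta_1/\theta_2}).
#' @param n_points number of measurement points (\eqn{n + 1}, including
#'   \eqn{t_0}).
#' @param dt inter-sample distance \eqn{\Delta t}.
#' @param observed observed species (indices or names); default all.
#' @param hidden_init_true start the hidden initial state at its true
#'   simulated value (otherwise at a perturbed value).
#' @param estimate_hidden optimise the hidden initial states (default); with
#'   `FALSE` they are held fixed at the true simulated value, for designs
#'   where the unobserved species' initial count is known.
#' @param sigma measurement-noise standard deviation added to the simulated
#'   counts (0 = noise-free).
#' @param estimate_sigma estimate \eqn{\sigma} jointly with \eqn{\theta}.
#' @param n_replicates number of replicate data sets.
#' @param base_seed integer base seed.
#' @param n_starts number of seeded optimiser starting points per replicate;
#'   all starts are run and the fit with the lowest objective value is kept
#'   (a guard against spurious local optima).
#' @param estimator `"extended"` (LNA covariance), `"constant"`
#'   (constant-variance predecessor) or `"exact_id"` (exact
#'   immigration-death maximum likelihood).
#' @param classify optionally restrict replicates to one qualitative
#'   trajectory class (`"normal"`, `"die_out"`, `"explode"`, see
#'   [classify_trajectory()]); candidate trajectories are generated with
#'   successive seeds until `n_replicates` of the class are found.
#' @param box parameter box, as in [mss_fit()].
#' @param model_args arguments for a named built-in model.
#' @param const_var constant variance for the `"constant"` estimator.
#' @param control optimiser control list.
#' @param max_events explosion guard for the exact simulation.
#' @return An object of class `"mss_scenario"`.
#' @export
mss_scenario <- function(model, theta_true, x0, n_points, dt,
                         observed = NULL, hidden_init_true = TRUE,
                         estimate_hidden = TRUE,
                         sigma = 0, estimate_sigma = FALSE,
                         n_replicates = 100, base_seed = 1, n_starts = 1,
                         estimator = c("extended", "constant", "exact_id"),
                         classify = NULL, box = c(1e-6, 100),
                         model_args = list(), const_var = 1,
                         control = list(), max_events = 1e7) {
  network <- if (is.character(model))
    do.call(builtin_network, c(list(name = model), model_args)) else model
  stopifnot(inherits(network, "reaction_network"),
            n_points >= 2, dt > 0, n_replicates >= 1)
  theta_true <- .check_theta(network, theta_true)
  if (identical(x0, "steady_state")) {
    if (network$name != "immigration-death")
      stop("'steady_state' start is defined for the immigration-death model")
    x0 <- round(theta_true[1] / theta_true[2])
  }
  structure(list(network = network, theta_true = theta_true, x0 = x0,
                 n_points = n_points, dt = dt, observed = observed,
                 hidden_init_true = hidden_init_true,
                 estimate_hidden = estimate_hidden, sigma = sigma,
                 estimate_sigma = estimate_sigma,
                 n_replicates = n_replicates, base_seed = base_seed,
                 n_starts = n_starts,
                 estimator = match.arg(estimator), classify = classify,
                 box = box, const_var = const_var, control = control,
                 max_events = max_events),
            class = "mss_scenario")
}

#' @export
print.mss_scenario <- function(x, ...) {
  cat(sprintf(
    "study scenario: %s, %d points at dt = %g, theta0 = (%s)\n%s estimator, %d replicates, base seed %d\n",
    x$network$name, x$n_points, x$dt,
    paste(signif(x$theta_true, 4), collapse = ", "),
    x$estimator, x$n_replicates, x$base_seed))
  invisible(x)
}

## simulate the data set for one replicate seed (SSA + optional noise + the
## perturbed optimiser start), all derived from that single seed
.replicate_inputs <- function(sc, seed) {
  set.seed(seed)
  t_grid <- sc$dt * (seq_len(sc$n_points) - 1L)
  ts <- ssa_simulate(sc$network, sc$x0, t_grid, sc$theta_true,
                     max_events = sc$max_events)
  if (sc$sigma > 0) {
    noisy <- ts$states + matrix(stats::rnorm(length(ts$states), 0, sc$sigma),
                                nrow(ts$states))
    ts_obs <- mss_timeseries(ts$times, noisy, species = ts$species)
    attr(ts_obs, "exploded") <- attr(ts, "exploded")
  } else ts_obs <- ts
  p <- sc$network$n_par
  theta_inits <- lapply(seq_len(sc$n_starts), function(s)
    sc$theta_true * stats::runif(p, 0.5, 2))
  obs_idx <- .resolve_observed(sc$network, ts, sc$observed)
  hid_idx <- setdiff(seq_along(sc$network$species), obs_idx)
  hidden_init <- NULL
  if (length(hid_idx)) {
    true_hid <- as.numeric(ts$states[1, hid_idx])
    hidden_init <- if (sc$hidden_init_true) true_hid
                   else pmax(true_hid * stats::runif(length(hid_idx), 0.5, 2), 1)
  }
  list(ts_clean = ts, ts = ts_obs, theta_inits = theta_inits,
       hidden_init = hidden_init, obs_idx = obs_idx)
}

## fit one replicate with the scenario's estimator; failures become
## non-converged rows, never errors.  With n_starts > 1 every seeded start is
## run and the lowest objective value wins: local optimisers can fall into
## spurious basins (e.g. the predator-free optimum of a partially observed
## predator-prey fit), and those basins score a far worse likelihood, so the
## best-of-k rule discards them whenever any start finds the real optimum.
.fit_replicate <- function(sc, inp) {
  one_fit <- function(theta_init) tryCatch(
    switch(sc$estimator,
      exact_id = id_mle(inp$ts, theta_init = theta_init, box = sc$box,
                        control = sc$control),
      mss_fit(inp$ts, sc$network, theta_init = theta_init,
              observed = inp$obs_idx, hidden_init = inp$hidden_init,
              estimate_hidden = sc$estimate_hidden,
              estimate_sigma = sc$estimate_sigma,
              sigma_meas = if (!sc$estimate_sigma && sc$sigma > 0) sc$sigma,
              variant = if (sc$estimator == "constant") "constant" else "lna",
              const_var = sc$const_var, box = sc$box, control = sc$control)),
    error = function(e) NULL)
  fit <- NULL
  for (theta_init in inp$theta_inits) {
    cand <- one_fit(theta_init)
    if (!is.null(cand) && (is.null(fit) || cand$value < fit$value))
      fit <- cand
  }
  if (is.null(fit))
    return(list(theta = rep(NA_real_, sc$network$n_par), sigma = NA_real_,
                value = NA_real_, converged = FALSE))
  list(theta = unname(fit$theta), sigma = fit$sigma %||% NA_real_,
       value = fit$value, converged = fit$converged)
}

#' Run a replicated simulation study
#'
#' For each replicate: generate an exact trajectory (plus optional
#' measurement noise), estimate the parameters with the scenario's
#' estimator, and record the estimate and its convergence status.  Summary
#' statistics (reported over the converged replicates only) are the average
#' estimate `av`, the average relative error
#' \eqn{ARE_j = \mathrm{mean}\, |\hat\theta_j - \theta_j^{(0)}| /
#' \theta_j^{(0)}}, the median relative error `medRE`, and the
#' non-convergence count `div`.  The whole study is reproducible from the
#' scenario alone; individual replicate failures are recorded as
#' non-converged, never aborting the study.
#'
#' @param scenario an [mss_scenario()].
#' @param verbose print per-replicate progress.
#' @return An object of class `"mss_study"`: estimates matrix
#'   (`n_replicates` rows), convergence flags, seeds, per-replicate
#'   objective values, summary statistics and the scenario.
#' @export
run_study <- function(scenario, verbose = FALSE) {
  sc <- scenario
  p <- sc$network$n_par
  est <- matrix(NA_real_, sc$n_replicates, p,
                dimnames = list(NULL, sc$network$theta_names))
  sig <- numeric(sc$n_replicates)
  val <- numeric(sc$n_replicates)
  conv <- logical(sc$n_replicates)
  seeds <- integer(sc$n_replicates)
  classes <- character(sc$n_replicates)

  i <- 0L
  attempt <- 0L
  while (i < sc$n_replicates) {
    attempt <- attempt + 1L
    if (attempt > 100L * sc$n_replicates)
      stop("could not find enough replicates of the requested class")
    seed <- sc$base_seed + attempt
    inp <- .replicate_inputs(sc, seed)
    cls <- classify_trajectory(inp$ts_clean)
    if (!is.null(sc$classify) && cls != sc$classify) next
    i <- i + 1L
    t0 <- proc.time()[3]
    res <- .fit_replicate(sc, inp)
    est[i, ] <- res$theta
    sig[i] <- res$sigma
    val[i] <- res$value
    conv[i] <- res$converged
    seeds[i] <- seed
    classes[i] <- cls
    if (verbose)
      message(sprintf("replicate %d/%d (seed %d): %s  [%.1fs]",
                      i, sc$n_replicates, seed,
                      if (res$converged) "converged" else "div",
                      proc.time()[3] - t0))
  }
  structure(list(estimates = est, sigma_estimates = sig, values = val,
                 converged = conv, seeds = seeds, classes = classes,
                 summary = study_summary_stats(est, conv, sc$theta_true),
                 scenario = sc),
            class = "mss_study")
}

#' Summary statistics of replicated estimates
#'
#' @param estimates replicate-by-parameter matrix of estimates.
#' @param converged logical convergence flags (statistics use converged
#'   replicates only).
#' @param theta_true true parameter vector.
#' @return A list with `av`, `ARE`, `medRE` (per-parameter vectors), `div`
#'   (non-converged count) and `n_converged`.
#' @export
study_summary_stats <- function(estimates, converged, theta_true) {
  estimates <- as.matrix(estimates)
  ok <- converged & stats::complete.cases(estimates)
  good <- estimates[ok, , drop = FALSE]
  rel <- sweep(abs(sweep(good, 2, theta_true)), 2, theta_true, "/")
  list(av = colMeans(good), ARE = colMeans(rel),
       medRE = apply(rel, 2, stats::median),
       div = sum(!ok), n_converged = sum(ok))
}

#' @export
print.mss_study <- function(x, digits = 4, ...) {
  print(x$scenario)
  s <- x$summary
  tab <- rbind(true = x$scenario$theta_true, av = s$av,
               `ARE (%)` = 100 * s$ARE, `medRE (%)` = 100 * s$medRE)
  colnames(tab) <- x$scenario$network$theta_names
  print(signif(tab, digits))
  cat(sprintf("div: %d of %d replicates\n", s$div,
              x$scenario$n_replicates))
  invisible(x)
}

#' @export
summary.mss_study <- function(object, ...) object$summary

#' Rank an external point estimate among the study's replicate estimates
#'
#' A multi-parameter estimate is scalarised to one sortable number as the
#' mean of its componentwise relative errors (the same structure as the
#' ARE); the external estimate's rank is 1 plus the number of converged
#' replicate estimates with a strictly smaller scalar error, so ties are
#' resolved in the external estimate's favour.
#'
#' @param study an [run_study()] result.
#' @param w external estimate vector.
#' @param theta_true true parameters (default: the scenario's).
#' @return Integer rank in `1 : (n_converged + 1)`.
#' @export
rank_external <- function(study, w, theta_true = NULL) {
  if (is.null(theta_true)) theta_true <- study$scenario$theta_true
  stopifnot(length(w) == length(theta_true))
  ok <- study$converged & stats::complete.cases(study$estimates)
  good <- study$estimates[ok, , drop = FALSE]
  scalar_err <- function(th) mean(abs(th - theta_true) / theta_true)
  we <- scalar_err(w)
  re <- apply(good, 1, scalar_err)
  1L + sum(re < we)
}

#' Write or read the study summary table
#'
#' A TSV mirroring the layout of the benchmark result tables (one row each
#' for the true value, av, ARE and medRE, plus the div count); numbers are
#' written with full precision so the file round-trips exactly.
#'
#' @param study an [run_study()] result.
#' @param path file path.
#' @return `write_study_table()` returns `path` invisibly;
#'   `read_study_table()` returns a data frame.
#' @export
write_study_table <- function(study, path) {
  s <- study$summary
  tab <- data.frame(statistic = c("true", "av", "ARE", "medRE"),
                    rbind(study$scenario$theta_true, s$av, s$ARE, s$medRE),
                    check.names = FALSE)
  names(tab)[-1] <- study$scenario$network$theta_names
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s | %d points, dt = %s | div = %d of %d",
                     study$scenario$network$name, study$scenario$n_points,
                     format(study$scenario$dt), s$div,
                     study$scenario$n_replicates), con)
  cols <- vapply(tab, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col),
    character(nrow(tab)))
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(apply(cols, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    colClasses = c(statistic = "character"))
}

#' Scatter plot of the replicate estimate cloud
#'
#' For two-parameter models, plots every converged replicate estimate with
#' the true parameter highlighted; for more parameters, shows all pairwise
#' clouds.  The elongation of the immigration-death cloud along the
#' \eqn{\theta_1/\theta_2} ray illustrates that the ratio is better
#' identified than the individual rates.
#'
#' @param x an [run_study()] result.
#' @param log plot on logarithmic axes (default true).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mss_study <- function(x, log = TRUE, ...) {
  ok <- x$converged & stats::complete.cases(x$estimates)
  good <- x$estimates[ok, , drop = FALSE]
  th <- x$scenario$theta_true
  nm <- x$scenario$network$theta_names
  if (nrow(good) == 0) return(invisible(x))
  p <- ncol(good)
  pairs <- if (p == 2) list(c(1, 2)) else
    utils::combn(p, 2, simplify = FALSE)
  if (length(pairs) > 1) {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(pairs)))
    on.exit(graphics::par(old))
  }
  for (pr in pairs) {
    graphics::plot(good[, pr[1]], good[, pr[2]], pch = 16, cex = 0.6,
                   log = if (log) "xy" else "",
                   xlab = nm[pr[1]], ylab = nm[pr[2]], ...)
    graphics::points(th[pr[1]], th[pr[2]], pch = 19, cex = 1.6,
                     col = "grey50")
  }
  invisible(x)
}
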