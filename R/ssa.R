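#' Time-series container
#'
#' A measurement grid \eqn{t_0 < t_1 < \dots < t_n} together with the
#' \eqn{(n+1) \times D} matrix of recorded species counts.  Exact simulation
#' produces non-negative integer states; measurement-noise data may be
#' real-valued.
#'
#' @param times strictly increasing numeric vector of length \eqn{n + 1}.
#' @param states numeric matrix with `length(times)` rows, one column per
#'   species.
#' @param species optional species labels (default: column names of
#'   `states`).
#' @return An object of class `"mss_timeseries"`: a list with elements
#'   `times`, `states` and `species`.
#' @export
mss_timeseries <- function(times, states, species = NULL) {
  times <- as.numeric(times)
  states <- as.matrix(states)
  storage.mode(states) <- "double"
  if (is.null(species)) species <- colnames(states)
  if (is.null(species)) species <- paste0("X", seq_len(ncol(states)))
  if (nrow(states) != length(times))
    stop("'states' must have one row per time point")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  colnames(states) <- species
  structure(list(times = times, states = states, species = species),
            class = "mss_timeseries")
}

#' @export
print.mss_timeseries <- function(x, ...) {
  cat(sprintf("time series: %d points on [%g, %g], species %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mss_timeseries <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Read and write time-series CSV files
#'
#' The on-disk format is a plain CSV with header `time,<species...>` and one
#' row per grid point; the writer/reader pair round-trips exactly.
#'
#' @param ts an [mss_timeseries()].
#' @param path file path.
#' @return `read_timeseries()` returns an [mss_timeseries()];
#'   `write_timeseries()` returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mss_timeseries(df$time, as.matrix(df[, -1, drop = FALSE]))
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates a reaction network as a continuous-time Markov jump process with
#' exponential waiting times (total hazard \eqn{\sum_k v_k}) and reaction
#' selection proportional to the individual hazards, and records the state on
#' a fixed measurement grid.  Sampling is right-continuous: the value stored
#' at \eqn{t_i} is the state immediately after the last event at time
#' \eqn{\le t_i}.
#'
#' @param network a [reaction_network()].
#' @param x0 non-negative integer initial state.
#' @param t_grid strictly increasing measurement times (the first entry is
#'   the initial time).
#' @param theta positive kinetic parameters.
#' @param seed optional integer seed; a given seed makes the trajectory fully
#'   reproducible.
#' @param max_events event-count ceiling guarding against explosion; when hit,
#'   the returned series carries `attr(, "exploded") = TRUE` and the remaining
#'   grid points repeat the last simulated state.
#' @return An [mss_timeseries()] of integer counts.
#' @export
ssa_simulate <- function(network, x0, t_grid, theta, seed = NULL,
                         max_events = 1e7) {
  x0 <- .check_state(network, x0)
  if (any(x0 != round(x0)))
    stop("'x0' must be an integer state")
  theta <- .check_theta(network, theta)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1 || (length(t_grid) > 1 && any(diff(t_grid) <= 0)))
    stop("'t_grid' must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)

  D <- length(x0)
  r <- ncol(network$S)
  n_grid <- length(t_grid)
  out <- matrix(0, n_grid, D)
  x <- x0
  t <- t_grid[1]
  out[1, ] <- x
  gi <- 2L
  n_events <- 0
  exploded <- FALSE

  while (gi <= n_grid) {
    v <- propensities(network, x, theta)
    v[v < 0] <- 0
    a0 <- sum(v)
    if (a0 <= 0) {
      ## absorbed: state stays constant forever
      out[gi:n_grid, ] <- matrix(x, n_grid - gi + 1, D, byrow = TRUE)
      break
    }
    t_next <- t + stats::rexp(1, a0)
    while (gi <= n_grid && t_grid[gi] < t_next) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    if (gi > n_grid) break
    k <- sample.int(r, 1L, prob = v)
    x <- x + network$S[, k]
    t <- t_next
    n_events <- n_events + 1
    if (n_events >= max_events) {
      exploded <- TRUE
      out[gi:n_grid, ] <- matrix(x, n_grid - gi + 1, D, byrow = TRUE)
      break
    }
  }
  ts <- mss_timeseries(t_grid, out, species = network$species)
  attr(ts, "exploded") <- exploded
  attr(ts, "n_events") <- n_events
  ts
}

#' Replicated exact simulations
#'
#' Generates `n_rep` independent trajectories with per-replicate seeds
#' `base_seed + 1, ..., base_seed + n_rep`, so any single replicate can be
#' regenerated in isolation.
#'
#' @inheritParams ssa_simulate
#' @param n_rep number of replicates.
#' @param base_seed integer base seed.
#' @return A list of [mss_timeseries()] objects.
#' @export
ssa_replicates <- function(network, x0, t_grid, theta, n_rep,
                           base_seed = 1, max_events = 1e7) {
  stopifnot(n_rep >= 1)
  lapply(seq_len(n_rep), function(i)
    ssa_simulate(network, x0, t_grid, theta, seed = base_seed + i,
                 max_events = max_events))
}

#' Reconstruct the eliminated conserved-moiety species
#'
#' For networks represented on a reduced species set with one moiety partner
#' eliminated through its conservation total (such as the auto-regulatory
#' network, where DNA.P2 = DNA_t - DNA), this returns the full state matrix
#' with the eliminated column restored.
#'
#' @param network a [reaction_network()] with an elimination record.
#' @param ts an [mss_timeseries()] over the reduced species.
#' @return A numeric matrix with the eliminated species appended.
#' @export
full_states <- function(network, ts) {
  el <- network$eliminated
  if (is.null(el))
    return(ts$states)
  extra <- el$total - ts$states[, el$partner]
  cbind(ts$states, matrix(extra, ncol = 1,
                          dimnames = list(NULL, el$species)))
}

#' Classify a trajectory as normal, die-out or exploding
#'
#' Stochastic predator-prey realisations divide qualitatively into
#' trajectories where the populations die out, where a population explodes,
#' and the rest.  `die-out` means every species is zero at the final grid
#' point; `explode` means the event ceiling was hit or any recorded count
#' exceeds `explode_threshold`.
#'
#' @param ts an [mss_timeseries()].
#' @param explode_threshold count threshold for the explosion label.
#' @return One of `"die_out"`, `"explode"`, `"normal"`.
#' @export
classify_trajectory <- function(ts, explode_threshold = 1e4) {
  if (isTRUE(attr(ts, "exploded")) || any(ts$states > explode_threshold))
    return("explode")
  if (all(ts$states[nrow(ts$states), ] == 0))
    return("die_out")
  "normal"
}
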