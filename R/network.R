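#' Mass-action reaction networks
#'
#' @description
#' `reaction_network()` builds the description of a chemical reaction network
#' with mass-action kinetics that every other function in the package consumes:
#' the species labels, the educt and product count matrices \eqn{q} and
#' \eqn{u}, the stoichiometric matrix \eqn{S = u - q}, the per-reaction rate
#' law descriptors and the system volume \eqn{\Omega}.
#'
#' Each reaction \eqn{k} has hazard
#' \deqn{v_k(x, \theta) = \theta_{p(k)} \prod_i f(b_i, q_{ik})}
#' where \eqn{b_i} is the count \eqn{x_i} of species \eqn{i} (or, for
#' moiety-complement factors, \eqn{T_i - x_i}), \eqn{f(b, e) = b^e} for plain
#' mass action, and \eqn{p(k)} maps reactions to kinetic parameters (the
#' identity by default).  Setting a reaction's `combinatorial` flag switches
#' \eqn{f} to the falling-factorial kernel \eqn{b(b-1)\cdots(b-e+1)/e!}.
#'
#' @param species character vector of the \eqn{D} species labels.
#' @param educts,products \eqn{D \times r} matrices of non-negative integer
#'   educt/product counts (rows = species, columns = reactions).
#' @param volume positive system volume \eqn{\Omega}; counts and
#'   concentrations coincide when `volume = 1` (the default).
#' @param rate_exponents optional \eqn{D \times r} matrix of rate-law
#'   exponents; defaults to `educts` (classical mass action).
#' @param complement_totals optional \eqn{D \times r} matrix; a non-negative
#'   entry \eqn{T} at `[i, k]` makes reaction `k` use the factor
#'   \eqn{(T - x_i)^{e}} instead of \eqn{x_i^{e}} (used for eliminated
#'   conserved-moiety partners).  `NA` entries (the default) are plain factors.
#' @param combinatorial optional logical \eqn{D \times r} matrix (or single
#'   logical) selecting the falling-factorial kernel per factor; default all
#'   `FALSE`.
#' @param param_map integer vector of length \eqn{r} mapping each reaction to
#'   a kinetic parameter index; defaults to `1:r`.
#' @param theta_names optional names for the kinetic parameters.
#' @param conserved optional list of conserved linear combinations, each a
#'   `list(coef = <length-D numeric>, total = <value>)` with
#'   \eqn{coef^\top S = 0}.
#' @param name short label for printing.
#'
#' @return An object of class `"reaction_network"`.
#' @seealso [immigration_death_network()], [autoreg_network()],
#'   [lotka_volterra_network()], [propensities()], [lna_moments()]
#' @export
reaction_network <- function(species, educts, products, volume = 1,
                             rate_exponents = NULL, complement_totals = NULL,
                             combinatorial = FALSE, param_map = NULL,
                             theta_names = NULL, conserved = NULL,
                             name = "reaction network") {
  species <- as.character(species)
  D <- length(species)
  educts <- as.matrix(educts)
  products <- as.matrix(products)
  if (!identical(dim(educts), dim(products)))
    stop("'educts' and 'products' must have identical dimensions")
  if (nrow(educts) != D)
    stop("count matrices must have one row per species")
  r <- ncol(educts)
  if (any(educts < 0) || any(products < 0) ||
      any(educts != round(educts)) || any(products != round(products)))
    stop("educt and product counts must be non-negative integers")
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("'volume' must be a positive scalar")

  if (is.null(rate_exponents)) rate_exponents <- educts
  rate_exponents <- as.matrix(rate_exponents)
  if (is.null(complement_totals))
    complement_totals <- matrix(NA_real_, D, r)
  complement_totals <- as.matrix(complement_totals)
  if (is.logical(combinatorial) && length(combinatorial) == 1L)
    combinatorial <- matrix(combinatorial, D, r)
  combinatorial <- as.matrix(combinatorial)
  stopifnot(identical(dim(rate_exponents), c(D, r)),
            identical(dim(complement_totals), c(D, r)),
            identical(dim(combinatorial), c(D, r)))

  if (is.null(param_map)) param_map <- seq_len(r)
  param_map <- as.integer(param_map)
  n_par <- max(param_map)
  if (length(param_map) != r || any(param_map < 1L))
    stop("'param_map' must be a positive integer vector of length r")
  if (is.null(theta_names)) theta_names <- paste0("theta", seq_len(n_par))
  if (length(theta_names) != n_par)
    stop("'theta_names' must have one entry per kinetic parameter")

  S <- products - educts
  storage.mode(S) <- "double"
  dimnames(S) <- list(species, NULL)

  if (!is.null(conserved)) {
    for (cv in conserved) {
      if (max(abs(drop(cv$coef %*% S))) > 1e-12)
        stop("conserved combination is not annihilated by the stoichiometry")
    }
  }

  structure(
    list(species = species, q = educts, u = products, S = S,
         volume = volume, rate_exponents = rate_exponents,
         complement_totals = complement_totals,
         combinatorial = combinatorial, param_map = param_map,
         n_par = n_par, theta_names = theta_names,
         conserved = conserved, eliminated = NULL, name = name),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("%s: %d species, %d reactions, %d parameters (volume %g)\n",
              x$name, length(x$species), ncol(x$S), x$n_par, x$volume))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

.check_state <- function(network, x) {
  D <- length(network$species)
  if (length(x) != D)
    stop(sprintf("state must have %d components", D))
  if (any(x < 0))
    stop("state components must be non-negative")
  as.numeric(x)
}

.check_theta <- function(network, theta) {
  if (length(theta) != network$n_par)
    stop(sprintf("theta must have %d components", network$n_par))
  as.numeric(theta)
}

#' Reaction hazards, drift Jacobian and diffusion matrix
#'
#' `propensities()` evaluates the mass-action hazard vector
#' \eqn{v(x, \theta)}.  `network_jacobian()` returns the \eqn{D \times D}
#' Jacobian \eqn{J = S \, dv/dx} of the deterministic drift \eqn{S v}, in
#' closed form.  `diffusion_matrix()` returns the symmetric positive
#' semi-definite matrix \eqn{D_{ij} = \sum_k S_{ik} S_{jk} v_k(x,\theta)}.
#' `ode_rhs()` is the drift \eqn{S v} itself.
#'
#' @param network a [reaction_network()].
#' @param x non-negative state vector (species counts).
#' @param theta positive kinetic parameter vector.
#' @return `propensities()`: length-\eqn{r} hazard vector;
#'   `network_jacobian()`, `diffusion_matrix()`: \eqn{D \times D} matrices;
#'   `ode_rhs()`: length-\eqn{D} drift vector.
#' @export
propensities <- function(network, x, theta) {
  x <- .check_state(network, x)
  theta <- .check_theta(network, theta)
  D <- length(x)
  r <- ncol(network$S)
  v <- theta[network$param_map]
  for (k in seq_len(r)) {
    for (i in seq_len(D)) {
      e <- network$rate_exponents[i, k]
      if (e > 0) {
        b <- if (is.na(network$complement_totals[i, k])) x[i]
             else network$complement_totals[i, k] - x[i]
        v[k] <- v[k] * if (network$combinatorial[i, k])
          prod(b - seq_len(e) + 1) / factorial(e) else b^e
      }
    }
  }
  v
}

#' @rdname propensities
#' @export
ode_rhs <- function(network, x, theta) {
  drop(network$S %*% propensities(network, x, theta))
}

#' @rdname propensities
#' @export
network_jacobian <- function(network, x, theta) {
  x <- .check_state(network, x)
  theta <- .check_theta(network, theta)
  D <- length(x)
  r <- ncol(network$S)
  dvdx <- matrix(0, r, D)
  for (k in seq_len(r)) {
    fac <- numeric(D)
    dfac <- numeric(D)
    for (i in seq_len(D)) {
      e <- network$rate_exponents[i, k]
      comp <- !is.na(network$complement_totals[i, k])
      b <- if (comp) network$complement_totals[i, k] - x[i] else x[i]
      sg <- if (comp) -1 else 1
      if (e <= 0) {
        fac[i] <- 1; dfac[i] <- 0
      } else if (network$combinatorial[i, k]) {
        terms <- b - seq_len(e) + 1
        fac[i] <- prod(terms) / factorial(e)
        dfac[i] <- sg * sum(vapply(seq_len(e), function(l)
          prod(terms[-l]), numeric(1))) / factorial(e)
      } else {
        fac[i] <- b^e
        dfac[i] <- sg * e * b^(e - 1)
      }
    }
    th <- theta[network$param_map[k]]
    for (i in seq_len(D))
      if (dfac[i] != 0)
        dvdx[k, i] <- th * dfac[i] * prod(fac[-i])
  }
  J <- network$S %*% dvdx
  dimnames(J) <- list(network$species, network$species)
  J
}

#' @rdname propensities
#' @export
diffusion_matrix <- function(network, x, theta) {
  v <- propensities(network, x, theta)
  Dm <- network$S %*% (v * t(network$S))
  Dm <- (Dm + t(Dm)) / 2
  dimnames(Dm) <- list(network$species, network$species)
  Dm
}

#' Built-in benchmark networks
#'
#' @description
#' Three standard small stochastic kinetics benchmarks:
#'
#' * `immigration_death_network()`: one species \eqn{X} with constant influx
#'   at rate \eqn{\theta_1} and linear decay at rate \eqn{\theta_2 x};
#'   stoichiometry \eqn{S = (1, -1)}.  The deterministic steady state is
#'   \eqn{\theta_1/\theta_2}, which is also the mean of the Poisson
#'   stationary law.
#' * `autoreg_network()`: a prokaryotic auto-regulatory gene network with a
#'   promoter that is reversibly sequestered by a protein dimer.  The full
#'   system has five species (DNA, P2, DNA.P2, mRNA, P) and the conserved
#'   moiety DNA + DNA.P2 = `dna_total`; it is represented here on the four
#'   independent species (DNA, P2, mRNA, P) with DNA.P2 eliminated via the
#'   total, so that the LNA covariance is non-singular.  Eight reactions with
#'   parameters \eqn{\theta_1 \ldots \theta_8}; the dimerisation
#'   \eqn{2P \to P_2} uses the hazard \eqn{\theta_5 P^2} so that the exact
#'   simulation, the ODE mean and the LNA share one kinetic convention
#'   (set `combinatorial_dimer = TRUE` for \eqn{\theta_5 P(P-1)/2}).
#' * `lotka_volterra_network()`: prey/predator system with prey reproduction,
#'   predation and predator death;
#'   \eqn{S = [[1, -1, 0], [0, 1, -1]]}.  Deterministic equilibrium
#'   \eqn{(\theta_3/\theta_2,\; \theta_1/\theta_2)}.
#'
#' @param dna_total positive integer total promoter copy number
#'   (DNA + DNA.P2); the benchmark scenarios use 2 and 10.
#' @param combinatorial_dimer use the combinatorial kernel
#'   \eqn{P(P-1)/2} for the dimerisation hazard instead of \eqn{P^2}.
#' @return A [reaction_network()].
#' @export
immigration_death_network <- function() {
  reaction_network(
    species = "X",
    educts = matrix(c(0, 1), 1, 2),
    products = matrix(c(1, 0), 1, 2),
    name = "immigration-death")
}

#' @rdname immigration_death_network
#' @export
autoreg_network <- function(dna_total = 10, combinatorial_dimer = FALSE) {
  if (!is.numeric(dna_total) || length(dna_total) != 1L || dna_total <= 0)
    stop("'dna_total' must be a positive number")
  sp <- c("DNA", "P2", "mRNA", "P")
  ## reactions: 1 DNA+P2 -> DNA.P2      2 DNA.P2 -> DNA+P2
  ##            3 DNA -> DNA+mRNA       4 mRNA -> 0
  ##            5 2P -> P2              6 P2 -> 2P
  ##            7 mRNA -> mRNA+P        8 P -> 0
  q <- matrix(0, 4, 8, dimnames = list(sp, NULL))
  u <- matrix(0, 4, 8, dimnames = list(sp, NULL))
  q["DNA", 1] <- 1; q["P2", 1] <- 1                    # educts of r1
  u["DNA", 2] <- 1; u["P2", 2] <- 1                    # products of r2
  q["DNA", 3] <- 1; u["DNA", 3] <- 1; u["mRNA", 3] <- 1
  q["mRNA", 4] <- 1
  q["P", 5] <- 2; u["P2", 5] <- 1
  q["P2", 6] <- 1; u["P", 6] <- 2
  q["mRNA", 7] <- 1; u["mRNA", 7] <- 1; u["P", 7] <- 1
  q["P", 8] <- 1
  ## reaction 2's educt is the eliminated complex DNA.P2 = dna_total - DNA:
  ## hazard theta2 * (dna_total - DNA), expressed as a complement factor.
  expo <- q
  expo["DNA", 2] <- 1
  ct <- matrix(NA_real_, 4, 8, dimnames = list(sp, NULL))
  ct["DNA", 2] <- dna_total
  comb <- matrix(FALSE, 4, 8, dimnames = list(sp, NULL))
  comb["P", 5] <- isTRUE(combinatorial_dimer)
  net <- reaction_network(
    species = sp, educts = q, products = u,
    rate_exponents = expo, complement_totals = ct, combinatorial = comb,
    name = sprintf("auto-regulatory gene network (DNA_t = %g)", dna_total))
  net$eliminated <- list(species = "DNA.P2", partner = "DNA",
                         total = dna_total)
  net
}

#' @rdname immigration_death_network
#' @export
lotka_volterra_network <- function() {
  ## r1: Y1 -> 2 Y1, r2: Y1 + Y2 -> 2 Y2, r3: Y2 -> 0
  reaction_network(
    species = c("Y1", "Y2"),
    educts = matrix(c(1, 0, 1, 1, 0, 1), 2, 3),
    products = matrix(c(2, 0, 0, 2, 0, 0), 2, 3),
    name = "Lotka-Volterra")
}

#' Look up a built-in network by name
#'
#' @param name one of `"immigration_death"`, `"autoreg"`, `"lotka_volterra"`.
#' @param ... passed to the builder (e.g. `dna_total` for `"autoreg"`).
#' @return A [reaction_network()].
#' @export
builtin_network <- function(name, ...) {
  switch(match.arg(name, c("immigration_death", "autoreg", "lotka_volterra")),
         immigration_death = immigration_death_network(),
         autoreg = autoreg_network(...),
         lotka_volterra = lotka_volterra_network())
}

#' Read or write a network definition file
#'
#' Networks are stored as JSON (or YAML, if the optional \pkg{yaml} package is
#' available and the file extension is `.yml`/`.yaml`) with keys `species`,
#' `volume`, and a `reactions` list whose entries give `educts` and `products`
#' as named counts, plus optional `exponents`, `complement_totals`,
#' `combinatorial` and `param` entries.  A top-level `builtin` key (with
#' optional `args`) refers to a built-in model by name instead.
#'
#' @param path file path.
#' @param network a [reaction_network()] (for writing).
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML network files requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.null(obj$builtin))
    return(do.call(builtin_network, c(list(name = obj$builtin),
                                      obj$args %||% list())))
  sp <- unlist(obj$species)
  D <- length(sp)
  r <- length(obj$reactions)
  grab <- function(field, default) {
    m <- matrix(default, D, r, dimnames = list(sp, NULL))
    for (k in seq_len(r)) {
      entry <- obj$reactions[[k]][[field]]
      if (!is.null(entry))
        m[names(entry), k] <- unlist(entry)
    }
    m
  }
  q <- grab("educts", 0)
  u <- grab("products", 0)
  expo <- grab("exponents", NA_real_)
  expo[is.na(expo)] <- q[is.na(expo)]
  ct <- grab("complement_totals", NA_real_)
  comb <- grab("combinatorial", 0) > 0
  reaction_network(species = sp, educts = q, products = u,
                   volume = obj$volume %||% 1,
                   rate_exponents = expo, complement_totals = ct,
                   combinatorial = comb,
                   name = obj$name %||% "reaction network")
}

#' @rdname read_network
#' @export
write_network <- function(network, path) {
  D <- length(network$species)
  reactions <- lapply(seq_len(ncol(network$S)), function(k) {
    nz <- function(vec) as.list(vec[vec != 0])
    out <- list(educts = nz(stats::setNames(network$q[, k], network$species)),
                products = nz(stats::setNames(network$u[, k], network$species)))
    if (!identical(network$rate_exponents[, k], network$q[, k]))
      out$exponents <- nz(stats::setNames(network$rate_exponents[, k],
                                          network$species))
    cts <- network$complement_totals[, k]
    if (any(!is.na(cts)))
      out$complement_totals <- as.list(stats::setNames(cts[!is.na(cts)],
                                                       network$species[!is.na(cts)]))
    if (any(network$combinatorial[, k]))
      out$combinatorial <- as.list(stats::setNames(
        as.numeric(network$combinatorial[network$combinatorial[, k], k]),
        network$species[network$combinatorial[, k]]))
    out
  })
  obj <- list(name = network$name, species = as.list(network$species),
              volume = network$volume, reactions = reactions)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML network files requires the 'yaml' package")
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
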