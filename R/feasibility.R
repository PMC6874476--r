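# Feasibility of a state over nutrient supply rates, via the steady-state mass
# conservation laws in the high-supply limit. Metabolite rows are ordered
# carbons 1..K then nitrogens 1..M; the unknown vector X pairs the abundances
# of present species (in species_id order) with the concentrations of
# metabolites not limiting anyone.

metab_names <- function(pool) {
  c(paste0("c", seq_len(pool$K)), paste0("n", seq_len(pool$M)))
}

# Row index (1..K+M) of the metabolite limiting each present species, and the
# complementary non-limiting metabolite rows.
limited_rows <- function(pool, state) {
  sp <- pool$species
  present <- which(state > 0L)
  rows <- ifelse(state[present] == 1L, sp$i[present], pool$K + sp$j[present])
  list(present = present, limited = rows,
       nonlim = setdiff(seq_len(pool$K + pool$M), rows))
}

#' Resource matrix of a community state
#'
#' Builds the square (K+M) x (K+M) matrix R_p of the steady-state mass
#' conservation laws phi / delta = R_p X_p in the high-supply limit. Each row
#' is one metabolite; each column is one entry of X_p: inverse yields 1/Y for
#' the abundance of every species consuming that metabolite, a single 1 on the
#' diagonal entry of each non-limiting metabolite's own concentration, zeros
#' elsewhere.
#'
#' @param pool a [species_pool()].
#' @param state integer state vector passing the exclusion rules.
#' @return numeric matrix with rownames `c1..cK, n1..nM` and one column per
#'   X entry (`B<species_id>` then non-limiting metabolite names).
#' @export
build_resource_matrix <- function(pool, state) {
  sp <- pool$species
  lr <- limited_rows(pool, state)
  D <- pool$K + pool$M
  if (length(lr$present) + length(lr$nonlim) != D) {
    stop("state violates rule 1: limited metabolites are not distinct")
  }
  R <- matrix(0, D, D)
  for (p in seq_along(lr$present)) {
    s <- lr$present[p]
    R[sp$i[s], p] <- 1 / sp$yield_c[s]
    R[pool$K + sp$j[s], p] <- 1 / sp$yield_n[s]
  }
  for (q in seq_along(lr$nonlim)) {
    R[lr$nonlim[q], length(lr$present) + q] <- 1
  }
  mn <- metab_names(pool)
  bnames <- if (length(lr$present)) paste0("B", sp$species_id[lr$present]) else character(0)
  dimnames(R) <- list(mn, c(bnames, mn[lr$nonlim]))
  R
}

#' Steady-state solution of a state at given supply rates
#'
#' Solves phi / delta = R_p X_p for the abundances of present species and the
#' concentrations of non-limiting metabolites. In the default high-supply mode
#' the (tiny) concentrations delta/lambda of limiting metabolites are dropped
#' from the conservation laws, exactly as used for all feasibility work; with
#' `exact = TRUE` they are retained on the right-hand side, which is the fixed
#' point the ODE system actually converges to.
#'
#' The state is feasible iff every entry of X_p is strictly positive.
#'
#' @param pool a [species_pool()].
#' @param state integer state vector.
#' @param supply numeric vector of K+M supply rates (carbons then nitrogens).
#' @param config a [model_config()].
#' @param exact keep limiting-metabolite concentrations delta/lambda?
#' @return object of class `state_solution`: list with `X` (named solution
#'   vector), `B` (length-S abundance vector, absent species 0), `conc`
#'   (length K+M metabolite concentrations), `feasible`, `exact`.
#' @export
solve_state <- function(pool, state, supply, config = model_config(), exact = FALSE) {
  sp <- pool$species
  D <- pool$K + pool$M
  stopifnot(length(supply) == D)
  R <- build_resource_matrix(pool, state)
  lr <- limited_rows(pool, state)
  rhs <- supply / config$delta
  lim_conc <- numeric(D)
  if (exact && length(lr$present) > 0) {
    lam <- ifelse(state[lr$present] == 1L,
                  sp$lambda_c[lr$present], sp$lambda_n[lr$present])
    lim_conc[lr$limited] <- config$delta / lam
    rhs <- rhs - lim_conc
  }
  X <- tryCatch(solve(R, rhs), error = function(e) {
    stop("degenerate state: resource matrix is singular (", conditionMessage(e), ")")
  })
  names(X) <- colnames(R)
  B <- numeric(pool$S)
  B[lr$present] <- X[seq_along(lr$present)]
  conc <- lim_conc
  conc[lr$nonlim] <- X[length(lr$present) + seq_along(lr$nonlim)]
  names(conc) <- metab_names(pool)
  structure(
    list(X = X, B = B, conc = conc,
         feasible = all(X > config$feas_tol), exact = exact),
    class = "state_solution"
  )
}

#' Sample nutrient supply vectors
#'
#' Independent uniform draws per metabolite from the configured supply box
#' (default \[10, 1000\]), the Monte-Carlo measure over environments used
#' throughout. The lower bound keeps the system in the high-supply regime.
#'
#' @param pool a [species_pool()].
#' @param n number of vectors.
#' @param config a [model_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric matrix (K+M) x n, rows named `c1..cK, n1..nM`.
#' @export
sample_supply <- function(pool, n, config = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- pool$K + pool$M
  m <- matrix(runif(D * n, config$supply_low, config$supply_high), nrow = D)
  rownames(m) <- metab_names(pool)
  m
}

#' Monte-Carlo feasibility of a set of states
#'
#' Samples supply vectors uniformly from the configured box and, for every
#' state, records at which samples all entries of X_p = R_p^{-1} phi / delta
#' are strictly positive. Each state's resource matrix is factorised once and
#' reused across all samples. The normalised feasible range of a state is the
#' fraction of samples at which it is feasible; states with singular resource
#' matrices (feasible only on a measure-zero set of supplies) are skipped with
#' a warning.
#'
#' @param pool a [species_pool()].
#' @param states integer state matrix (one row per state).
#' @param config a [model_config()]; `config$n_samples` sets the sample count
#'   unless `n_samples` is given.
#' @param seed integer seed for the supply sample.
#' @param n_samples optional override of the sample count.
#' @param supply optional precomputed (K+M) x n supply matrix (overrides
#'   sampling; used to re-evaluate the same environments).
#' @return object of class `feasibility_report`: list with `states`,
#'   `fraction` (per state), `feasible` (per state, integer vector of sample
#'   ids), `supply`, `n_samples`, `delta`.
#' @export
monte_carlo_feasibility <- function(pool, states, config = model_config(),
                                    seed = NULL, n_samples = NULL, supply = NULL) {
  if (is.null(supply)) {
    if (is.null(n_samples)) n_samples <- config$n_samples
    supply <- sample_supply(pool, n_samples, config, seed = seed)
  } else {
    n_samples <- ncol(supply)
  }
  n_states <- nrow(states)
  feasible <- vector("list", n_states)
  fraction <- numeric(n_states)
  phi <- supply / config$delta
  for (p in seq_len(n_states)) {
    Rinv <- tryCatch(solve(build_resource_matrix(pool, states[p, ])),
                     error = function(e) NULL)
    if (is.null(Rinv)) {
      warning("state ", p, " has a singular resource matrix; skipped")
      feasible[[p]] <- integer(0)
      fraction[p] <- NA_real_
      next
    }
    X <- Rinv %*% phi
    ids <- which(colSums(X <= config$feas_tol) == 0L)
    feasible[[p]] <- ids
    fraction[p] <- length(ids) / n_samples
  }
  structure(
    list(states = states, fraction = fraction, feasible = feasible,
         supply = supply, n_samples = n_samples, delta = config$delta),
    class = "feasibility_report"
  )
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf(
    "feasibility report: %d states x %d supply samples\n  feasible fractions: min %.3g, median %.3g, max %.3g\n",
    nrow(x$states), x$n_samples,
    min(x$fraction, na.rm = TRUE), stats::median(x$fraction, na.rm = TRUE),
    max(x$fraction, na.rm = TRUE)
  ))
  invisible(x)
}

# Invert a feasibility report restricted to a subset of states: for each
# sample with at least one feasible state, the indices (into `subset`) of the
# states feasible there.
sample_state_sets <- function(report, subset = seq_len(nrow(report$states))) {
  pairs_state <- rep(seq_along(subset),
                     lengths(report$feasible[subset]))
  pairs_sample <- unlist(report$feasible[subset], use.names = FALSE)
  if (length(pairs_sample) == 0) return(list(sets = list(), samples = integer(0)))
  o <- order(pairs_sample)
  sets <- split(pairs_state[o], pairs_sample[o])
  list(sets = sets, samples = as.integer(names(sets)))
}

#' Structural stability calls from feasible fractions
#'
#' A state is structurally stable when its normalised feasible range (fraction
#' of sampled supply-rate combinations at which it is feasible) exceeds the
#' threshold, 0.1 by convention.
#'
#' @param report a [monte_carlo_feasibility()] report.
#' @param threshold feasible-range cutoff.
#' @return logical vector per state (`NA` for degenerate states).
#' @export
classify_structural_stability <- function(report, threshold = 0.1) {
  report$fraction > threshold
}
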