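# Chemostat dynamics: Liebig growth, the coupled population/nutrient ODE
# system, stiff integration with extinction clamping, and mapping converged
# trajectories back to community-state labels.

#' Liebig growth rate of one species
#'
#' Growth is set by the scarcer of the two essential resources:
#' `min(lambda_c * c, lambda_n * n)`. The attribute `"limiting"` reports which
#' resource sets the rate (`"carbon"` or `"nitrogen"`); an exact tie is
#' flagged `"tie"` (measure-zero for generic parameters).
#'
#' @param species one row of `pool$species` (or any list with `lambda_c`,
#'   `lambda_n`).
#' @param c,n non-negative concentrations of the species' carbon and nitrogen
#'   resources.
#' @return growth rate (1/time) with attribute `"limiting"`.
#' @export
growth_rate <- function(species, c, n) {
  if (c < 0 || n < 0) stop("negative concentration")
  gc <- species$lambda_c * c
  gn <- species$lambda_n * n
  limiting <- if (gc < gn) "carbon" else if (gn < gc) "nitrogen" else "tie"
  structure(min(gc, gn), limiting = limiting)
}

# deSolve right-hand side. State vector y = (B_1..B_S, c_1..c_K, n_1..n_M).
make_rhs <- function(pool, supply, config) {
  sp <- pool$species
  K <- pool$K; M <- pool$M; S <- pool$S
  # aggregation matrices: consumption of each metabolite from per-species uptake
  Ac <- matrix(0, K, S); Ac[cbind(sp$i, seq_len(S))] <- 1
  An <- matrix(0, M, S); An[cbind(sp$j, seq_len(S))] <- 1
  delta <- config$delta
  function(t, y, parms) {
    y <- pmax(y, 0)
    B <- y[seq_len(S)]
    cc <- y[S + seq_len(K)]
    nn <- y[S + K + seq_len(M)]
    g <- pmin(sp$lambda_c * cc[sp$i], sp$lambda_n * nn[sp$j])
    dB <- B * (g - delta)
    uptake <- B * g
    dc <- supply[seq_len(K)] - delta * cc - as.vector(Ac %*% (uptake / sp$yield_c))
    dn <- supply[K + seq_len(M)] - delta * nn - as.vector(An %*% (uptake / sp$yield_n))
    list(c(dB, dc, dn))
  }
}

#' Time derivatives of the chemostat system
#'
#' The coupled ODEs: each population grows at its Liebig rate minus dilution,
#' `dB/dt = B (g - delta)`; each metabolite is supplied at a fixed rate,
#' diluted, and consumed by every species using it at rate `B g / Y`.
#'
#' @param pool a [species_pool()].
#' @param supply numeric vector of K+M supply rates (carbons then nitrogens).
#' @param state numeric vector `(B_1..B_S, c_1..c_K, n_1..n_M)`, non-negative.
#' @param config a [model_config()].
#' @return numeric vector of time derivatives in the same order.
#' @export
ode_rhs <- function(pool, supply, state, config = model_config()) {
  stopifnot(length(supply) == pool$K + pool$M,
            length(state) == pool$S + pool$K + pool$M)
  if (any(state < 0)) stop("negative abundances/concentrations")
  make_rhs(pool, supply, config)(0, state, NULL)[[1]]
}

#' Integrate the community dynamics
#'
#' Stiff (BDF) integration of the chemostat system. Integration proceeds in
#' chunks; after each chunk, any population below the extinction threshold is
#' clamped to exactly zero and stays there (once extinct, `dB/dt = 0`), which
#' keeps near-extinction transients from stalling the solver.
#'
#' @param pool a [species_pool()].
#' @param supply numeric vector of K+M supply rates.
#' @param init initial `(B, c, n)` vector; or a `state_solution` from
#'   [solve_state()], whose abundances and concentrations are used.
#' @param t_end integration horizon.
#' @param config a [model_config()].
#' @param n_chunks extinction-clamping chunks.
#' @param n_out stored time points.
#' @return object of class `cr_trajectory`: list with `times` and `states`
#'   (matrix, one row per time, columns `B* , c*, n*`).
#' @export
integrate_community <- function(pool, supply, init, t_end,
                                config = model_config(),
                                n_chunks = 20, n_out = 200) {
  if (inherits(init, "state_solution")) init <- c(init$B, init$conc)
  S <- pool$S; D <- pool$K + pool$M
  stopifnot(t_end > 0, length(init) == S + D)
  rhs <- make_rhs(pool, supply, config)
  y <- pmax(as.numeric(init), 0)
  edges <- seq(0, t_end, length.out = n_chunks + 1)
  per <- max(2, ceiling(n_out / n_chunks) + 1)
  out_t <- numeric(0)
  out_y <- NULL
  for (k in seq_len(n_chunks)) {
    times <- seq(edges[k], edges[k + 1], length.out = per)
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = "bdf", rtol = config$rtol, atol = config$atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed near t = ", max(sol[, 1]))
    }
    keep <- if (k == 1) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- pmax(sol[nrow(sol), -1], 0)
    y[seq_len(S)][y[seq_len(S)] < config$extinction_threshold] <- 0
  }
  colnames(out_y) <- c(paste0("B", pool$species$species_id), metab_names(pool))
  structure(list(times = out_t, states = out_y, pool_dims = c(S = S, K = pool$K, M = pool$M)),
            class = "cr_trajectory")
}

#' @export
print.cr_trajectory <- function(x, ...) {
  cat(sprintf("community trajectory: %d time points on [0, %g], %d variables\n",
              length(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' Map a converged trajectory to its community state
#'
#' Declares the trajectory converged when the relative change of every
#' variable over the last tenth of the time window is below `tolerance`
#' (non-converged trajectories raise a "transient" error; extend `t_end` and
#' retry). Surviving species are those above the extinction threshold, each
#' labelled by its Liebig-limiting resource at the endpoint. An exact
#' limitation tie cannot be labelled and raises an error.
#'
#' @param trajectory a [integrate_community()] result.
#' @param pool a [species_pool()].
#' @param config a [model_config()].
#' @param tolerance convergence tolerance on the relative change.
#' @return integer state vector (codes 0 absent / 1 carbon- / 2
#'   nitrogen-limited).
#' @export
classify_endpoint <- function(trajectory, pool, config = model_config(),
                              tolerance = 1e-6) {
  y <- trajectory$states
  nt <- nrow(y)
  win <- y[seq(max(1, floor(0.9 * nt)), nt), , drop = FALSE]
  span <- apply(win, 2, function(v) diff(range(v)))
  scale <- pmax(abs(y[nt, ]), 1e-8)
  if (any(span / scale > tolerance)) {
    stop("transient: trajectory has not converged (max relative change ",
         signif(max(span / scale), 3), "); extend t_end")
  }
  end <- y[nt, ]
  sp <- pool$species
  B <- end[seq_len(pool$S)]
  cc <- end[pool$S + seq_len(pool$K)]
  nn <- end[pool$S + pool$K + seq_len(pool$M)]
  state <- integer(pool$S)
  for (s in which(B > config$extinction_threshold)) {
    gc <- sp$lambda_c[s] * cc[sp$i[s]]
    gn <- sp$lambda_n[s] * nn[sp$j[s]]
    if (abs(gc - gn) <= 1e-6 * max(gc, gn)) {
      stop("limitation tie for species ", sp$species_id[s],
           ": cannot label the limiting resource")
    }
    state[s] <- if (gc < gn) 1L else 2L
  }
  state
}
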