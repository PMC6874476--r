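# Dynamic stability of steady states: direct perturbation + integration for
# small systems, and inference from state-multiplicity patterns (the V/(V-1)
# rule with iterative repair) for large ones.

#' Direct dynamic-stability test of one state
#'
#' At each supplied supply vector, starts the system at the state's exact
#' fixed point (limiting concentrations delta/lambda retained), applies an
#' ensemble of random multiplicative perturbations to the abundances of
#' present species and to all metabolite concentrations, and integrates. The
#' state is dynamically stable iff every run returns to the same community
#' state and the same solution; it is unstable if any run converges to a
#' different state. Only species present in the state are perturbed: an
#' invadable state would trivially be destabilised by introducing an invader,
#' and that is a different notion of stability.
#'
#' The verdict is expected to be independent of the supply point; a mixed
#' outcome across points triggers a warning (and the unstable verdict).
#'
#' @param pool a [species_pool()].
#' @param state integer state vector, feasible at every supply point.
#' @param supply_points numeric (K+M) x n_points matrix (or a single vector).
#' @param config a [model_config()]; `perturbation_magnitude` sets the
#'   relative perturbation size.
#' @param n_perturb perturbations per supply point.
#' @param t_end initial integration horizon (doubled up to `max_doublings`
#'   times if the trajectory is still transient).
#' @param max_doublings horizon-extension cap.
#' @param return_tol relative L-infinity distance to the fixed point below
#'   which a run counts as returned.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `label` (`"stable"`, `"unstable"` or `"unknown"`),
#'   `method = "direct_ode"`, and `runs` (data.frame of per-run outcomes).
#' @export
test_dynamic_stability <- function(pool, state, supply_points,
                                   config = model_config(),
                                   n_perturb = 20, t_end = 200,
                                   max_doublings = 3, return_tol = 1e-4,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(supply_points))) supply_points <- matrix(supply_points, ncol = 1)
  m <- config$perturbation_magnitude
  key <- state_key(state)
  present <- which(state > 0L)
  runs <- list()
  for (pt in seq_len(ncol(supply_points))) {
    supply <- supply_points[, pt]
    sol <- solve_state(pool, state, supply, config, exact = TRUE)
    if (!sol$feasible) {
      stop("state is not feasible at supply point ", pt)
    }
    for (r in seq_len(n_perturb)) {
      init <- c(sol$B, sol$conc)
      init[present] <- init[present] * (1 + runif(length(present), -m, m))
      nc <- pool$S + seq_len(pool$K + pool$M)
      init[nc] <- init[nc] * (1 + runif(length(nc), -m, m))
      horizon <- t_end
      end_state <- NULL
      for (dbl in 0:max_doublings) {
        traj <- integrate_community(pool, supply, init, horizon, config)
        end_state <- tryCatch(classify_endpoint(traj, pool, config),
                              error = function(e) NULL)
        if (!is.null(end_state)) break
        horizon <- horizon * 2
      }
      if (is.null(end_state)) {
        runs[[length(runs) + 1]] <- data.frame(point = pt, run = r,
                                               returned = NA, end_key = NA)
        next
      }
      returned <- identical(state_key(end_state), key)
      if (returned) {
        endB <- traj$states[nrow(traj$states), seq_len(pool$S)]
        rel <- abs(endB[present] - sol$B[present]) / pmax(sol$B[present], 1e-12)
        returned <- max(rel) < return_tol
      }
      runs[[length(runs) + 1]] <- data.frame(point = pt, run = r,
                                             returned = returned,
                                             end_key = state_key(end_state))
    }
  }
  runs <- do.call(rbind, runs)
  per_point <- tapply(runs$returned, runs$point, function(v) all(v %in% TRUE))
  if (length(unique(per_point[!is.na(per_point)])) > 1) {
    warning("stability verdict differs between supply points")
  }
  label <- if (any(runs$returned %in% FALSE)) "unstable"
  else if (all(runs$returned %in% TRUE)) "stable"
  else "unknown"
  list(label = label, method = "direct_ode", runs = runs)
}

#' Infer dynamic stability from multiplicity patterns
#'
#' For pools too large for direct integration, stability of uninvadable states
#' is inferred from the Monte-Carlo feasibility record. A state that is the
#' unique feasible uninvadable state at some sampled supply must be
#' dynamically stable (every environment needs at least one stable endpoint);
#' the remaining feasible states are potentially unstable. Empirically, V
#' feasible stable states are accompanied by V-1 feasible unstable ones at
#' every supply point (the V/(V-1) rule); violations of this rule are repaired
#' iteratively by reclassifying, at each step, the potentially-unstable state
#' implicated in the most violating samples as stable, whenever doing so
#' lowers the total violation count (ties broken by the smallest state index).
#' States never feasible in the sample stay `"unknown"`.
#'
#' @param report a [monte_carlo_feasibility()] report computed over the
#'   uninvadable states.
#' @return data.frame with `state_id` (row in `report$states`), `label`,
#'   `method`; attributes `pre_repair_violations`, `post_repair_violations`,
#'   `n_reclassified`, `n_zero_feasible_samples`.
#' @export
infer_stability <- function(report) {
  n_states <- nrow(report$states)
  n_samples <- report$n_samples
  feas <- report$feasible
  ntot <- integer(n_samples)
  for (p in seq_len(n_states)) ntot[feas[[p]]] <- ntot[feas[[p]]] + 1L
  any_feas <- ntot > 0L
  unique_somewhere <- vapply(seq_len(n_states), function(p) {
    length(feas[[p]]) > 0 && any(ntot[feas[[p]]] == 1L)
  }, logical(1))
  ever <- lengths(feas) > 0
  label <- ifelse(!ever, "unknown", ifelse(unique_somewhere, "stable", "unstable"))
  method <- rep("inferred_unique_point", n_states)

  ns <- integer(n_samples); nu <- integer(n_samples)
  for (p in which(label == "stable")) ns[feas[[p]]] <- ns[feas[[p]]] + 1L
  for (p in which(label == "unstable")) nu[feas[[p]]] <- nu[feas[[p]]] + 1L
  viol <- any_feas & (nu != ns - 1L)
  pre <- sum(viol)
  n_re <- 0L
  repeat {
    total <- sum(viol)
    if (total == 0L) break
    cand <- which(label == "unstable")
    if (length(cand) == 0) break
    counts <- vapply(cand, function(p) sum(viol[feas[[p]]]), integer(1))
    ord <- cand[order(-counts, cand)]
    ord <- ord[counts[order(-counts, cand)] > 0]
    improved <- FALSE
    for (p in ord) {
      idx <- feas[[p]]
      ns2 <- ns[idx] + 1L
      nu2 <- nu[idx] - 1L
      newv <- nu2 != ns2 - 1L
      if (total + sum(newv) - sum(viol[idx]) < total) {
        ns[idx] <- ns2; nu[idx] <- nu2; viol[idx] <- newv
        label[p] <- "stable"
        method[p] <- "inferred_violation_repair"
        n_re <- n_re + 1L
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  structure(
    data.frame(state_id = seq_len(n_states), label = label, method = method),
    pre_repair_violations = pre,
    post_repair_violations = sum(viol),
    n_reclassified = n_re,
    n_zero_feasible_samples = sum(!any_feas)
  )
}
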