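# Community states are coded as integer vectors of length S:
#   0 = absent, 1 = carbon-limited, 2 = nitrogen-limited.
# Sets of states are integer matrices with one row per state.

#' State helpers
#'
#' A community state assigns each pool species one of three roles: absent,
#' present and limited by its carbon metabolite, or present and limited by its
#' nitrogen metabolite (codes 0, 1, 2). `state_richness()` counts surviving
#' species per state; `state_key()` gives a canonical string label.
#'
#' @param states integer matrix (rows = states) or a single integer vector.
#' @return `state_richness()`: integer vector; `state_key()`: character vector.
#' @export
state_richness <- function(states) {
  if (is.null(dim(states))) sum(states > 0) else as.integer(rowSums(states > 0))
}

#' @rdname state_richness
#' @export
state_key <- function(states) {
  if (is.null(dim(states))) paste(states, collapse = "") else
    apply(states, 1, paste, collapse = "")
}

#' All raw species/limiting-nutrient assignments
#'
#' Every map species -> \{absent, carbon-limited, nitrogen-limited\}, i.e. the
#' 3^S theoretical maximum of distinct states, as a matrix with 3^S rows. This
#' is the brute-force substrate: filtering it through the exclusion rules must
#' reproduce the structured enumeration exactly.
#'
#' @param pool a [species_pool()] with at most 12 species (3^S rows are
#'   materialised; larger pools must use the structured search).
#' @return integer matrix (3^S x S) of state codes.
#' @export
candidate_assignments <- function(pool) {
  S <- pool$S
  if (S > 12) {
    stop("3^", S, " assignments is too many to materialise; use the structured search")
  }
  as.matrix(expand.grid(rep(list(0:2), S), KEEP.OUT.ATTRS = FALSE))
}

#' Test a state against the competitive exclusion rules
#'
#' Rule 1: each metabolite limits the growth of at most one species. Rule 2:
#' every species using a metabolite non-limitingly must be strictly more
#' competitive for it (larger lambda) than the species whose growth that
#' metabolite limits. States violating either rule cannot be steady states.
#'
#' @param pool a [species_pool()].
#' @param state integer state vector (codes 0/1/2, length S).
#' @return logical; attribute `"violations"` lists the broken rules.
#' @export
satisfies_exclusion_rules <- function(pool, state) {
  ok <- rules_filter(pool, matrix(as.integer(state), nrow = 1), report = TRUE)
  structure(ok$ok, violations = ok$violations[[1]])
}

# Vectorised Rules 1-2 filter over an assignment matrix.
rules_filter <- function(pool, A, report = FALSE) {
  sp <- pool$species
  n <- nrow(A)
  ok <- rep(TRUE, n)
  viol <- if (report) replicate(n, character(0), simplify = FALSE) else NULL
  flag <- function(bad, msg) {
    ok[bad] <<- FALSE
    if (report) for (r in which(bad)) viol[[r]] <<- c(viol[[r]], msg)
  }
  for (i in seq_len(pool$K)) {
    cols <- which(sp$i == i)
    if (length(cols) == 0) next
    lim <- A[, cols, drop = FALSE] == 1L
    flag(rowSums(lim) > 1, sprintf("rule 1: carbon %d limits more than one species", i))
    for (a in cols) for (b in setdiff(cols, a)) {
      if (sp$lambda_c[b] < sp$lambda_c[a]) {
        flag(A[, a] == 1L & A[, b] == 2L,
             sprintf("rule 2: species %d uses carbon %d non-limitingly but is less competitive than species %d",
                     sp$species_id[b], i, sp$species_id[a]))
      }
    }
  }
  for (j in seq_len(pool$M)) {
    cols <- which(sp$j == j)
    if (length(cols) == 0) next
    lim <- A[, cols, drop = FALSE] == 2L
    flag(rowSums(lim) > 1, sprintf("rule 1: nitrogen %d limits more than one species", j))
    for (a in cols) for (b in setdiff(cols, a)) {
      if (sp$lambda_n[b] < sp$lambda_n[a]) {
        flag(A[, a] == 2L & A[, b] == 1L,
             sprintf("rule 2: species %d uses nitrogen %d non-limitingly but is less competitive than species %d",
                     sp$species_id[b], j, sp$species_id[a]))
      }
    }
  }
  list(ok = ok, violations = viol)
}

#' Enumerate all steady states of a pool
#'
#' Returns every state consistent with the competitive exclusion rules. The
#' structured search iterates over all selections of carbon-limited species
#' (per carbon metabolite: each consumer, or nobody), eliminates species
#' out-competed on their carbon, and then per nitrogen metabolite enumerates
#' the admissible nitrogen-limited additions (any surviving consumer less
#' competitive for that nitrogen than all carbon-limited species using it) plus
#' the empty choice. The brute-force method filters all 3^S raw assignments
#' and is used as an independent oracle in tests.
#'
#' The empty community (no species) satisfies both rules vacuously and is
#' retained, flagged by the `"trivial"` attribute.
#'
#' @param pool a [species_pool()].
#' @param method `"structured"` (default) or `"brute"`.
#' @return integer matrix of states (rows sorted by canonical key), with
#'   attribute `"trivial"`: logical vector marking the empty state.
#' @export
enumerate_steady_states <- function(pool, method = c("structured", "brute")) {
  method <- match.arg(method)
  sp <- pool$species
  if (method == "brute") {
    A <- candidate_assignments(pool)
    states <- A[rules_filter(pool, A)$ok, , drop = FALSE]
  } else {
    byC <- lapply(seq_len(pool$K), function(i) which(sp$i == i))
    n_sel <- prod(vapply(byC, length, 0L) + 1)
    if (n_sel > 1e6) {
      stop("too many carbon-limited selections (", n_sel,
           "); full steady-state enumeration is only supported for small pools")
    }
    choice_grid <- expand.grid(lapply(byC, function(v) c(0L, v)),
                               KEEP.OUT.ATTRS = FALSE)
    rows <- list()
    for (r in seq_len(nrow(choice_grid))) {
      climited <- as.integer(choice_grid[r, ])   # row index into sp, 0 = none
      base <- integer(pool$S)
      base[climited[climited > 0]] <- 1L
      lim_of_carbon <- climited[sp$i]            # per species: limiter of its carbon
      dead <- lim_of_carbon > 0 & base != 1L &
        sp$lambda_c < ifelse(lim_of_carbon > 0, sp$lambda_c[pmax(lim_of_carbon, 1)], Inf)
      adm <- vector("list", pool$M)
      for (j in seq_len(pool$M)) {
        users <- which(sp$j == j)
        clim_users <- users[base[users] == 1L]
        thresh <- if (length(clim_users)) min(sp$lambda_n[clim_users]) else Inf
        cand <- users[base[users] != 1L & !dead[users] & sp$lambda_n[users] < thresh]
        adm[[j]] <- c(0L, cand)
      }
      combos <- expand.grid(adm, KEEP.OUT.ATTRS = FALSE)
      block <- matrix(rep(base, nrow(combos)), nrow = nrow(combos), byrow = TRUE)
      for (j in seq_len(pool$M)) {
        added <- as.integer(combos[, j])
        has <- added > 0L
        block[cbind(which(has), added[has])] <- 2L
      }
      rows[[r]] <- block
    }
    states <- do.call(rbind, rows)
    states <- states[!duplicated(state_key(states)), , drop = FALSE]
  }
  ord <- order(state_richness(states), state_key(states))
  states <- states[ord, , drop = FALSE]
  dimnames(states) <- list(NULL, paste0("sp", sp$species_id))
  attr(states, "trivial") <- state_richness(states) == 0L
  states
}

#' Greedy construction of the uninvadable state for one carbon selection
#'
#' Given a choice of carbon-limited species (at most one per carbon
#' metabolite), first eliminates every species out-competed on its carbon, then
#' for each nitrogen metabolite adds the surviving non-carbon-limited consumer
#' with the largest lambda_n as nitrogen-limited. The construction succeeds iff
#' for every nitrogen that top candidate is less competitive than all
#' carbon-limited species using the same nitrogen; otherwise that candidate
#' would invade any state built on this carbon selection and no uninvadable
#' state exists for it.
#'
#' @param pool a [species_pool()].
#' @param c_selection integer vector of length K: `species_id` of the
#'   carbon-limited species per carbon metabolite, or `NA` for none.
#' @return list with `exists` (logical), `state` (integer state vector or
#'   `NULL`) and, on failure, `blocker` (the species_id that invades).
#' @export
construct_uninvadable <- function(pool, c_selection) {
  sp <- pool$species
  stopifnot(length(c_selection) == pool$K)
  state <- integer(pool$S)
  for (i in seq_len(pool$K)) {
    sid <- c_selection[i]
    if (is.na(sid)) next
    row <- which(sp$species_id == sid)
    if (length(row) != 1 || sp$i[row] != i) {
      stop("c_selection[", i, "] is not a consumer of carbon ", i)
    }
    state[row] <- 1L
  }
  lim_row <- integer(pool$K)                   # row of carbon limiter, 0 = none
  lim_row[sp$i[state == 1L]] <- which(state == 1L)
  dead <- state != 1L & lim_row[sp$i] > 0 &
    sp$lambda_c < ifelse(lim_row[sp$i] > 0, sp$lambda_c[pmax(lim_row[sp$i], 1)], Inf)
  for (j in seq_len(pool$M)) {
    users <- which(sp$j == j)
    clim_users <- users[state[users] == 1L]
    thresh <- if (length(clim_users)) min(sp$lambda_n[clim_users]) else Inf
    cand <- users[state[users] != 1L & !dead[users]]
    if (length(cand) == 0) next
    best <- cand[which.max(sp$lambda_n[cand])]
    if (sp$lambda_n[best] < thresh) {
      state[best] <- 2L
    } else {
      return(list(exists = FALSE, state = NULL, blocker = sp$species_id[best]))
    }
  }
  list(exists = TRUE, state = state)
}

#' Invadability of a community state
#'
#' A state is uninvadable if no pool species absent from it can grow in the
#' environment the state sets. In the high-supply regime a candidate invader
#' succeeds iff it can grow on both of its resources: each resource is either
#' not limiting anyone (abundant) or limits a species less competitive for it
#' than the invader. The verdict depends only on the rank order of competitive
#' abilities, not on supply rates.
#'
#' @param pool a [species_pool()].
#' @param state integer state vector passing [satisfies_exclusion_rules()].
#' @return list with `uninvadable` (logical) and `invaders` (species_id vector
#'   of successful invaders).
#' @export
is_uninvadable <- function(pool, state) {
  sp <- pool$species
  lim_c <- rep(NA_integer_, pool$K)
  lim_n <- rep(NA_integer_, pool$M)
  lim_c[sp$i[state == 1L]] <- which(state == 1L)
  lim_n[sp$j[state == 2L]] <- which(state == 2L)
  absent <- which(state == 0L)
  inv <- vapply(absent, function(s) {
    cl <- lim_c[sp$i[s]]
    nl <- lim_n[sp$j[s]]
    c_ok <- is.na(cl) || sp$lambda_c[s] > sp$lambda_c[cl]
    n_ok <- is.na(nl) || sp$lambda_n[s] > sp$lambda_n[nl]
    c_ok && n_ok
  }, logical(1))
  list(uninvadable = !any(inv), invaders = sp$species_id[absent[inv]])
}

#' Enumerate all uninvadable states
#'
#' Applies the greedy construction of [construct_uninvadable()] over every
#' selection of carbon-limited species (exhaustive search, implemented in
#' compiled code). Each carbon selection admits at most one uninvadable state,
#' so the result has at most prod_i (consumers of carbon i + 1) rows. On small
#' pools the output equals filtering [enumerate_steady_states()] through
#' [is_uninvadable()].
#'
#' @param pool a [species_pool()].
#' @return integer matrix of uninvadable states (one row each), sorted
#'   canonically; the empty state is flagged via attribute `"trivial"`.
#' @export
enumerate_uninvadable <- function(pool) {
  sp <- pool$species
  states <- enumerate_uninvadable_cpp(pool$K, pool$M, sp$i, sp$j,
                                      sp$lambda_c, sp$lambda_n)
  states <- states[!duplicated(state_key(states)), , drop = FALSE]
  ord <- order(state_richness(states), state_key(states))
  states <- states[ord, , drop = FALSE]
  dimnames(states) <- list(NULL, paste0("sp", sp$species_id))
  attr(states, "trivial") <- state_richness(states) == 0L
  states
}
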