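#' Construct a species pool
#'
#' A species pool holds the K carbon metabolites, M nitrogen metabolites and S
#' specialist species of the model. Each species consumes exactly one carbon
#' and one nitrogen metabolite; its traits are the competitive abilities
#' `lambda_c`, `lambda_n` (growth rate per unit resource concentration) and the
#' yields `yield_c`, `yield_n` (biomass concentration per unit resource
#' consumed). The ratio `yield_n / yield_c` is the species' C:N stoichiometry.
#'
#' Competitive abilities must be pairwise distinct within every resource
#' column: all enumeration logic depends only on the rank order of the lambdas,
#' and ties would make the outcome of competition undefined. Tied pools are
#' rejected rather than broken arbitrarily. Several species may share a
#' resource pair (the classic two-species, two-essential-resources setting);
#' full K x M grids with one specialist per pair are merely the common case.
#'
#' @param species data.frame with columns `species_id`, `i` (carbon index),
#'   `j` (nitrogen index), `lambda_c`, `lambda_n`, `yield_c`, `yield_n`.
#' @param K,M numbers of carbon and nitrogen metabolites. Default: the largest
#'   index used.
#' @return an object of class `species_pool`: a list with elements `K`, `M`,
#'   `S` and the validated `species` data.frame.
#' @seealso [generate_pool()], [load_pool()], [competitiveness_ranks()]
#' @export
species_pool <- function(species, K = max(species$i), M = max(species$j)) {
  required <- c("species_id", "i", "j", "lambda_c", "lambda_n", "yield_c", "yield_n")
  missing <- setdiff(required, names(species))
  if (length(missing) > 0) {
    stop("species table lacks column(s): ", paste(missing, collapse = ", "))
  }
  species <- species[, required]
  species$species_id <- as.integer(species$species_id)
  species$i <- as.integer(species$i)
  species$j <- as.integer(species$j)
  if (anyDuplicated(species$species_id)) stop("duplicate species_id")
  if (any(species$i < 1L) || any(species$i > K)) stop("carbon index out of [1..K]")
  if (any(species$j < 1L) || any(species$j > M)) stop("nitrogen index out of [1..M]")
  traits <- as.matrix(species[, c("lambda_c", "lambda_n", "yield_c", "yield_n")])
  if (!all(is.finite(traits)) || any(traits <= 0)) {
    stop("all trait values must be finite and strictly positive")
  }
  for (i in seq_len(K)) {
    lam <- species$lambda_c[species$i == i]
    if (anyDuplicated(lam)) {
      stop("tie in competitive abilities: lambda_c repeated on carbon ", i)
    }
  }
  for (j in seq_len(M)) {
    lam <- species$lambda_n[species$j == j]
    if (anyDuplicated(lam)) {
      stop("tie in competitive abilities: lambda_n repeated on nitrogen ", j)
    }
  }
  species <- species[order(species$species_id), , drop = FALSE]
  rownames(species) <- NULL
  structure(
    list(K = as.integer(K), M = as.integer(M), S = nrow(species), species = species),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf(
    "species pool: %dC x %dN x %dS\n", x$K, x$M, x$S
  ))
  print(head(x$species, 10))
  if (x$S > 10) cat("...", x$S - 10, "more species\n")
  invisible(x)
}

#' Generate a random species pool
#'
#' Draws one specialist species for every (carbon, nitrogen) metabolite pair,
#' so `S = K * M`. Competitive abilities are drawn uniformly from
#' `lambda_range` (default \[10, 100\]) and yields uniformly from `yield_range`
#' (default \[0.1, 1\]). On the measure-zero event of a lambda tie within a
#' resource column the whole pool is redrawn.
#'
#' @param K,M numbers of carbon and nitrogen metabolites (>= 1).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param lambda_range,yield_range length-2 numeric intervals, strictly
#'   positive and increasing.
#' @return a [species_pool()].
#' @examples
#' pool <- generate_pool(2, 2, seed = 1)
#' pool$S   # 4 species
#' @export
generate_pool <- function(K, M, seed = NULL,
                          lambda_range = c(10, 100),
                          yield_range = c(0.1, 1)) {
  if (K < 1 || M < 1) stop("K and M must be >= 1")
  check_range <- function(r, what) {
    if (length(r) != 2 || !all(is.finite(r)) || any(r <= 0) || r[1] >= r[2]) {
      stop(what, " must be a strictly positive increasing interval")
    }
  }
  check_range(lambda_range, "lambda_range")
  check_range(yield_range, "yield_range")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    grid <- expand.grid(j = seq_len(M), i = seq_len(K))[, c("i", "j")]
    S <- nrow(grid)
    species <- data.frame(
      species_id = seq_len(S),
      i = grid$i, j = grid$j,
      lambda_c = runif(S, lambda_range[1], lambda_range[2]),
      lambda_n = runif(S, lambda_range[1], lambda_range[2]),
      yield_c = runif(S, yield_range[1], yield_range[2]),
      yield_n = runif(S, yield_range[1], yield_range[2])
    )
    ok <- !any(vapply(seq_len(K), function(i) {
      anyDuplicated(species$lambda_c[species$i == i]) > 0
    }, logical(1))) && !any(vapply(seq_len(M), function(j) {
      anyDuplicated(species$lambda_n[species$j == j]) > 0
    }, logical(1)))
    if (ok) return(species_pool(species, K = K, M = M))
  }
}

#' Read / write species pools as delimited text
#'
#' Pool files are plain CSV with the header
#' `species_id,i,j,lambda_c,lambda_n,yield_c,yield_n`, one row per species.
#' Loading validates the pool (positivity, distinct resource pairs, no lambda
#' ties within a resource column); a save/load round trip reproduces the pool
#' at printed precision.
#'
#' @param path file path.
#' @param K,M optional metabolite counts (default: largest index present).
#' @return `load_pool()` returns a [species_pool()]; `save_pool()` invisibly
#'   returns `path`.
#' @export
load_pool <- function(path, K = NULL, M = NULL) {
  tab <- read.csv(path)
  if (is.null(K)) K <- max(tab$i)
  if (is.null(M)) M <- max(tab$j)
  species_pool(tab, K = K, M = M)
}

#' @rdname load_pool
#' @param pool a [species_pool()].
#' @export
save_pool <- function(pool, path) {
  stopifnot(inherits(pool, "species_pool"))
  write.csv(pool$species, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Competitiveness ranks of all species
#'
#' Within each resource column, species consuming that resource are ranked by
#' their competitive ability: rank 1 is the largest lambda. A species' average
#' competitiveness rank is the mean of its carbon and nitrogen ranks; the
#' double top competitor has average rank 1, the double bottom competitor of a
#' full L x L pool has average rank L (or 5.5 for ranks 5 and 6).
#'
#' @param pool a [species_pool()].
#' @return data.frame with `species_id`, `rank_c`, `rank_n`, `average_rank`.
#' @export
competitiveness_ranks <- function(pool) {
  sp <- pool$species
  rank_c <- integer(nrow(sp))
  rank_n <- integer(nrow(sp))
  for (i in seq_len(pool$K)) {
    idx <- which(sp$i == i)
    rank_c[idx] <- rank(-sp$lambda_c[idx])
  }
  for (j in seq_len(pool$M)) {
    idx <- which(sp$j == j)
    rank_n[idx] <- rank(-sp$lambda_n[idx])
  }
  data.frame(
    species_id = sp$species_id,
    rank_c = rank_c, rank_n = rank_n,
    average_rank = (rank_c + rank_n) / 2
  )
}

#' Global model configuration
#'
#' Collects the chemostat and simulation parameters shared across the package.
#' Defaults keep the model in the high-supply regime: with dilution rate
#' `delta = 1` and lambda >= 10, the largest limiting concentration
#' `delta^2 / lambda = 0.1` is far below the lower supply bound 10, so
#' invadability depends only on the rank order of competitive abilities.
#'
#' @param delta chemostat dilution rate (1/time).
#' @param supply_low,supply_high bounds of the uniform supply-rate sampling box
#'   (per metabolite).
#' @param n_samples Monte-Carlo supply samples.
#' @param perturbation_magnitude relative size of stability perturbations.
#' @param rtol,atol ODE integration tolerances.
#' @param extinction_threshold abundance below which a species is clamped to 0.
#' @param feas_tol strict-positivity tolerance for feasibility decisions.
#' @param lambda_min smallest competitive ability the pool may contain; used
#'   only to check the high-supply invariant
#'   `supply_low >= 100 * delta^2 / lambda_min`.
#' @return an object of class `model_config` (a list).
#' @export
model_config <- function(delta = 1,
                         supply_low = 10, supply_high = 1000,
                         n_samples = 1e5,
                         perturbation_magnitude = 0.01,
                         rtol = 1e-8, atol = 1e-10,
                         extinction_threshold = 1e-9,
                         feas_tol = 1e-12,
                         lambda_min = 10) {
  if (supply_low <= 0 || supply_high <= supply_low) {
    stop("supply bounds must satisfy 0 < supply_low < supply_high")
  }
  if (supply_low < 100 * delta^2 / lambda_min) {
    stop(
      "high-supply regime violated: need supply_low >= 100 * delta^2 / lambda_min (= ",
      100 * delta^2 / lambda_min, ")"
    )
  }
  structure(
    list(
      delta = delta, supply_low = supply_low, supply_high = supply_high,
      n_samples = as.integer(n_samples),
      perturbation_magnitude = perturbation_magnitude,
      rtol = rtol, atol = atol,
      extinction_threshold = extinction_threshold,
      feas_tol = feas_tol, lambda_min = lambda_min
    ),
    class = "model_config"
  )
}
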