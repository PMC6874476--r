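# Downstream community statistics: multistability counts and the Poisson fit,
# supply-balance scans, richness / prevalence / feasible-range relationships,
# the yield-variation sweep, and the PCA projection of state abundances.

#' Multistability statistics over sampled environments
#'
#' V is the number of uninvadable dynamically stable states simultaneously
#' feasible at a sampled supply vector. Every environment should have V >= 1
#' (some stable endpoint exists); samples with V = 0 are counted in an
#' attribute and excluded from the fit. V - 1, the number of extra states, is
#' fitted by a Poisson distribution; the maximum-likelihood rate is the mean
#' of V - 1.
#'
#' @param report a [monte_carlo_feasibility()] report over uninvadable states.
#' @param labels stability labels aligned with `report$states`.
#' @return object of class `multistability_stats`: list with `V` (per sample),
#'   `histogram` (table of V), `poisson_rate`, `ratio` (per-sample supply
#'   balance sum phi_c / sum phi_n), `n_samples`; attribute
#'   `n_zero_stable_samples`.
#' @export
multistability_histogram <- function(report, labels) {
  stable_ids <- which(labels$label == "stable")
  n <- report$n_samples
  V <- integer(n)
  for (p in stable_ids) V[report$feasible[[p]]] <- V[report$feasible[[p]]] + 1L
  K <- sum(startsWith(rownames(report$supply), "c"))
  ratio <- colSums(report$supply[seq_len(K), , drop = FALSE]) /
    colSums(report$supply[-seq_len(K), , drop = FALSE])
  ok <- V >= 1L
  structure(
    list(V = V, histogram = table(factor(V[ok], levels = 0:max(V))),
         poisson_rate = mean(V[ok] - 1L), ratio = ratio, n_samples = n),
    class = "multistability_stats",
    n_zero_stable_samples = sum(!ok)
  )
}

#' @export
print.multistability_stats <- function(x, ...) {
  cat(sprintf(
    "multistability over %d environments: max V = %d, Poisson rate for V-1 = %.4f\n",
    x$n_samples, max(x$V), x$poisson_rate
  ))
  print(x$histogram)
  invisible(x)
}

#' Multistability versus supply balance
#'
#' Bins the per-sample carbon:nitrogen supply ratio (log10 scale) and reports
#' the fraction of multistable samples (V >= 2) per bin. The peak sits near
#' the balanced supply matching the average species stoichiometry.
#'
#' @param stats a [multistability_histogram()] result.
#' @param n_bins number of log-ratio bins.
#' @return data.frame `log10_ratio` (bin midpoint), `n`, `fraction_multistable`;
#'   attribute `peak` gives the bin midpoint with the largest fraction.
#' @export
multistability_vs_balance <- function(stats, n_bins = 25) {
  lr <- log10(stats$ratio)
  breaks <- seq(min(lr), max(lr), length.out = n_bins + 1)
  bin <- cut(lr, breaks, include.lowest = TRUE)
  multi <- stats$V >= 2L
  out <- data.frame(
    log10_ratio = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n = as.integer(table(bin)),
    fraction_multistable = as.numeric(tapply(multi, bin, mean))
  )
  out$fraction_multistable[is.na(out$fraction_multistable) & out$n == 0] <- NA
  structure(out, peak = out$log10_ratio[which.max(out$fraction_multistable)])
}

#' Diversity, prevalence and structural-stability statistics
#'
#' Computes the relationships between supply balance, species richness,
#' species prevalence and feasible range:
#' \describe{
#'   \item{`richness_vs_balance`}{mean (and sd of) richness of feasible stable
#'     states per log10 supply-ratio bin, over (sample, state) incidences.}
#'   \item{`prevalence`}{per species: fraction of samples at which it is
#'     present in at least one feasible uninvadable state (`prevalence_any`),
#'     and in every feasible uninvadable state (`prevalence_all`), joined with
#'     its competitiveness ranks.}
#'   \item{`states_by_richness`}{number of dynamically stable and unstable
#'     uninvadable states at each richness.}
#'   \item{`range_vs_richness`}{summary of the feasible ranges of stable
#'     states at each richness.}
#' }
#'
#' @param report a [monte_carlo_feasibility()] report over uninvadable states.
#' @param labels stability labels aligned with `report$states`.
#' @param pool the [species_pool()].
#' @param n_bins log-ratio bins for the richness panel.
#' @return list of the four data.frames (class `diversity_stats`).
#' @export
richness_and_range_stats <- function(report, labels, pool, n_bins = 25) {
  states <- report$states
  rich <- state_richness(states)
  stable_ids <- which(labels$label == "stable")
  K <- pool$K

  # mean richness per supply-ratio bin, over (sample, feasible stable state)
  inc_sample <- unlist(report$feasible[stable_ids], use.names = FALSE)
  inc_rich <- rep(rich[stable_ids], lengths(report$feasible[stable_ids]))
  lr <- log10(colSums(report$supply[seq_len(K), , drop = FALSE]) /
                colSums(report$supply[-seq_len(K), , drop = FALSE]))
  breaks <- seq(min(lr), max(lr), length.out = n_bins + 1)
  bin <- cut(lr[inc_sample], breaks, include.lowest = TRUE)
  richness_vs_balance <- data.frame(
    log10_ratio = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n = as.integer(table(bin)),
    mean_richness = as.numeric(tapply(inc_rich, bin, mean)),
    sd_richness = as.numeric(tapply(inc_rich, bin, sd))
  )

  # species prevalence across sampled environments
  n <- report$n_samples
  n_any <- integer(pool$S)
  n_all <- integer(pool$S)
  tot <- integer(n)
  for (p in seq_len(nrow(states))) tot[report$feasible[[p]]] <-
    tot[report$feasible[[p]]] + 1L
  n_with <- sum(tot > 0)
  for (s in seq_len(pool$S)) {
    holders <- which(states[, s] > 0L)
    cnt <- integer(n)
    for (p in holders) cnt[report$feasible[[p]]] <- cnt[report$feasible[[p]]] + 1L
    n_any[s] <- sum(cnt > 0L)
    n_all[s] <- sum(tot > 0L & cnt == tot)
  }
  prevalence <- cbind(
    competitiveness_ranks(pool),
    prevalence_any = n_any / n,
    prevalence_all = n_all / max(n_with, 1)
  )

  states_by_richness <- as.data.frame(table(
    richness = factor(rich, levels = 0:max(rich)),
    label = labels$label
  ))

  sr <- rich[stable_ids]
  fr <- report$fraction[stable_ids]
  range_vs_richness <- do.call(rbind, lapply(sort(unique(sr)), function(r) {
    f <- fr[sr == r]
    data.frame(richness = r, n_states = length(f),
               min = min(f), q25 = quantile(f, 0.25), median = stats::median(f),
               q75 = quantile(f, 0.75), max = max(f), mean = mean(f))
  }))
  rownames(range_vs_richness) <- NULL

  structure(
    list(richness_vs_balance = richness_vs_balance,
         prevalence = prevalence,
         states_by_richness = states_by_richness,
         range_vs_richness = range_vs_richness),
    class = "diversity_stats"
  )
}

#' Multistability as a function of stoichiometry variation
#'
#' Re-draws all species yields from progressively wider uniform intervals
#' while keeping the competitive abilities fixed, and records for each variant
#' the spread of species stoichiometries (sd of log10 of the yield ratio
#' Y(n)/Y(c)) together with the fraction of sampled supply vectors admitting
#' multistability (V >= 2 feasible uninvadable stable states). Species with
#' identical stoichiometries admit no multistability at all, so narrow
#' intervals produce mostly zero fractions.
#'
#' @param pool base [species_pool()]; its lambdas are kept, its yields are
#'   replaced per variant.
#' @param yield_intervals list of length-2 intervals to draw yields from.
#' @param n_variants_per_interval variants per interval.
#' @param n_samples Monte-Carlo supply samples per variant.
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return data.frame `variant`, `interval`, `stoich_sd`,
#'   `multistable_fraction` (class `yield_sweep`).
#' @export
yield_variation_sweep <- function(pool,
                                  yield_intervals = list(
                                    c(0.45, 0.55), c(0.3, 0.7),
                                    c(0.1, 0.9), c(0.01, 1.0)
                                  ),
                                  n_variants_per_interval = 1000,
                                  n_samples = 1e5,
                                  config = model_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  v_id <- 0L
  for (iv in yield_intervals) {
    for (v in seq_len(n_variants_per_interval)) {
      v_id <- v_id + 1L
      sp <- pool$species
      sp$yield_c <- runif(pool$S, iv[1], iv[2])
      sp$yield_n <- runif(pool$S, iv[1], iv[2])
      variant <- species_pool(sp, K = pool$K, M = pool$M)
      states <- enumerate_uninvadable(variant)
      rep_v <- monte_carlo_feasibility(variant, states, config,
                                       n_samples = n_samples)
      labels <- infer_stability(rep_v)
      stats <- multistability_histogram(rep_v, labels)
      rows[[v_id]] <- data.frame(
        variant = v_id,
        interval = paste0("U(", iv[1], ",", iv[2], ")"),
        stoich_sd = sd(log10(sp$yield_n / sp$yield_c)),
        multistable_fraction = mean(stats$V >= 2L)
      )
    }
  }
  structure(do.call(rbind, rows), class = c("yield_sweep", "data.frame"))
}

#' Column-normalised heatmap of a yield sweep
#'
#' Logarithmic binning of stoichiometry spread (x) and multistable fraction
#' (y) into `n_bins` bins each; counts are normalised to sum to 100 within
#' each column. Variants with zero multistability are collected in a separate
#' bottom row.
#'
#' @param sweep a [yield_variation_sweep()] result.
#' @param n_bins bins per axis.
#' @return matrix (rows = fraction bins, bottom row `"0"`; columns = spread
#'   bins) of column percentages.
#' @export
yield_sweep_heatmap <- function(sweep, n_bins = 50) {
  x <- log10(pmax(sweep$stoich_sd, 1e-6))
  xb <- cut(x, seq(min(x), max(x), length.out = n_bins + 1), include.lowest = TRUE)
  pos <- sweep$multistable_fraction > 0
  ylog <- log10(sweep$multistable_fraction[pos])
  if (length(ylog) > 0) {
    ybreaks <- seq(min(ylog), max(ylog), length.out = n_bins + 1)
    yb <- cut(ylog, ybreaks, include.lowest = TRUE)
    ylev <- levels(yb)
  } else {
    yb <- factor(character(0), levels = paste0("y", seq_len(n_bins)))
    ylev <- levels(yb)
  }
  m <- matrix(0, n_bins + 1, n_bins, dimnames = list(c("0", ylev), levels(xb)))
  m["0", ] <- table(xb[!pos])
  if (length(ylog) > 0) m[-1, ] <- table(yb, xb[pos])
  sums <- colSums(m)
  sums[sums == 0] <- 1
  base::sweep(m, 2, sums / 100, "/")
}

#' PCA projection of state abundances in a fluctuating environment
#'
#' Emulates repeated sampling of a microbial ecosystem around one environment:
#' supply rates are jittered uniformly within a relative window (default
#' +/-10%) of the centre, every feasible uninvadable state at each jittered
#' supply contributes its relative species abundances, and the pooled
#' abundance table is projected on its first two principal components.
#' Dynamically unstable states are included and tagged: in the projection they
#' interleave between the stable clusters.
#'
#' @param pool a [species_pool()].
#' @param states integer matrix of uninvadable states.
#' @param labels stability labels aligned with `states`.
#' @param center_supply numeric vector of K+M supply rates (e.g. a sampled
#'   environment with the largest V).
#' @param jitter_fraction relative half-width of the supply window.
#' @param n_samples jittered environments.
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return data.frame `sample`, `state_id`, `label`, `PC1`, `PC2`; attribute
#'   `var_explained`.
#' @export
pca_state_projection <- function(pool, states, labels, center_supply,
                                 jitter_fraction = 0.1, n_samples = 500,
                                 config = model_config(), seed = NULL) {
  if (n_samples < 3) stop("need at least 3 samples")
  if (!is.null(seed)) set.seed(seed)
  D <- pool$K + pool$M
  supply <- matrix(
    center_supply * (1 + runif(D * n_samples, -jitter_fraction, jitter_fraction)),
    nrow = D
  )
  rows <- list()
  meta <- list()
  for (p in seq_len(nrow(states))) {
    R <- tryCatch(build_resource_matrix(pool, states[p, ]), error = function(e) NULL)
    if (is.null(R)) next
    present <- which(states[p, ] > 0L)
    if (length(present) == 0) next
    X <- solve(R, supply / config$delta)
    ok <- which(colSums(X <= config$feas_tol) == 0L)
    if (length(ok) == 0) next
    B <- matrix(0, length(ok), pool$S)
    B[, present] <- t(X[seq_along(present), ok, drop = FALSE])
    B <- B / rowSums(B)
    rows[[length(rows) + 1]] <- B
    meta[[length(meta) + 1]] <- data.frame(sample = ok, state_id = p,
                                           label = labels$label[p])
  }
  if (length(rows) == 0) stop("no state is feasible in the jittered neighbourhood")
  mat <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  out <- cbind(meta, PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(out, var_explained = ve[1:2])
}
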