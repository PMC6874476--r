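test_that("the Poisson rate is the mean number of extra states and is recoverable", {
  # synthetic record: V - 1 drawn Poisson(0.1) over 4000 samples, states
  # assigned arbitrarily; the MLE must recover the rate within 3 sigma
  set.seed(42)
  n <- 4000L
  V <- 1L + stats::rpois(n, 0.1)
  n_states <- 8L
  feas <- replicate(n_states, integer(0), simplify = FALSE)
  labels <- data.frame(state_id = 1:8,
                       label = rep(c("stable", "unstable"), each = 4),
                       method = "inferred_unique_point")
  for (s in seq_len(n)) {
    picked <- sample(1:4, V[s])
    for (p in picked) feas[[p]] <- c(feas[[p]], s)
  }
  supply <- matrix(runif(4 * n, 10, 1000), nrow = 4,
                   dimnames = list(c("c1", "c2", "n1", "n2"), NULL))
  fake <- structure(list(states = matrix(0L, n_states, 4), feasible = feas,
                         fraction = lengths(feas) / n, supply = supply,
                         n_samples = n),
                    class = "feasibility_report")
  stats <- multistability_histogram(fake, labels)
  expect_equal(stats$V, V)
  se <- sqrt(0.1 / n)
  expect_lt(abs(stats$poisson_rate - 0.1), 3 * se)
  expect_equal(sum(stats$histogram), n)
})

test_that("balance scan fractions are proportions peaking inside the ratio range", {
  pool <- generate_pool(4, 4, seed = 1)
  ui <- enumerate_uninvadable(pool)
  rep1 <- monte_carlo_feasibility(pool, ui, model_config(n_samples = 5000),
                                  seed = 2)
  lab <- infer_stability(rep1)
  stats <- multistability_histogram(rep1, lab)
  scan <- multistability_vs_balance(stats, n_bins = 15)
  frac <- scan$fraction_multistable[scan$n > 0]
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(sum(scan$n), 5000)
  expect_true(attr(scan, "peak") >= min(scan$log10_ratio) &&
                attr(scan, "peak") <= max(scan$log10_ratio))

  # equal stoichiometry: no multistability in any bin
  ep <- equal_stoich_pool(2, 2, seed = 3)
  er <- monte_carlo_feasibility(ep, enumerate_uninvadable(ep),
                                model_config(n_samples = 2000), seed = 4)
  el <- infer_stability(er)
  escan <- multistability_vs_balance(multistability_histogram(er, el), n_bins = 10)
  expect_true(all(escan$fraction_multistable[escan$n > 0] == 0))
})

test_that("diversity statistics connect richness, prevalence and feasible range", {
  pool <- generate_pool(4, 4, seed = 1)
  ui <- enumerate_uninvadable(pool)
  rep1 <- monte_carlo_feasibility(pool, ui, model_config(n_samples = 5000),
                                  seed = 2)
  lab <- infer_stability(rep1)
  ds <- richness_and_range_stats(rep1, lab, pool, n_bins = 15)

  # richness of any state is bounded by the number of metabolites
  expect_true(all(state_richness(ui) <= pool$K + pool$M))
  ok <- !is.na(ds$richness_vs_balance$mean_richness)
  expect_true(all(ds$richness_vs_balance$mean_richness[ok] <= pool$K + pool$M))

  # the double top competitor is present in every sampled environment
  rk <- competitiveness_ranks(pool)
  if (any(rk$average_rank == 1)) {
    top <- which(rk$average_rank == 1)
    expect_true(all(ds$prevalence$prevalence_any[top] == 1))
    expect_true(all(ds$prevalence$prevalence_all[top] == 1))
  }
  expect_true(all(ds$prevalence$prevalence_any >= ds$prevalence$prevalence_all))
  expect_true(all(ds$prevalence$prevalence_any >= 0 &
                    ds$prevalence$prevalence_any <= 1))

  # state counts by richness add up; range summaries ordered
  expect_equal(sum(ds$states_by_richness$Freq), nrow(ui))
  expect_true(all(ds$range_vs_richness$min <= ds$range_vs_richness$median &
                    ds$range_vs_richness$median <= ds$range_vs_richness$max))
})

test_that("yield variation drives multistability and equal yields forbid it", {
  pool <- keystone_pool()   # lambda ranks admit the bistable switch
  sweep <- yield_variation_sweep(
    pool,
    yield_intervals = list(c(0.45, 0.55), c(0.05, 1.0)),
    n_variants_per_interval = 6, n_samples = 1500,
    config = model_config(), seed = 5
  )
  expect_equal(nrow(sweep), 12)
  expect_true(all(sweep$multistable_fraction >= 0 &
                    sweep$multistable_fraction <= 1))
  # wider yield intervals give a larger stoichiometry spread on average
  expect_lt(mean(sweep$stoich_sd[1:6]), mean(sweep$stoich_sd[7:12]))
  # with the switch available, wide yield draws do produce multistability
  expect_gt(sum(sweep$multistable_fraction[7:12] > 0), 0)

  hm <- yield_sweep_heatmap(sweep, n_bins = 5)
  sums <- colSums(hm)
  expect_true(all(abs(sums[sums > 0] - 100) < 1e-9))

  # an exactly equal-stoichiometry variant has no multistable environments
  ep <- equal_stoich_pool(2, 2, seed = 7)
  er <- monte_carlo_feasibility(ep, enumerate_uninvadable(ep),
                                model_config(n_samples = 2000), seed = 8)
  el <- infer_stability(er)
  expect_equal(mean(multistability_histogram(er, el)$V >= 2), 0)
})

test_that("the PCA projection clusters by state and tags stability", {
  pool <- generate_pool(4, 4, seed = 1)
  ui <- enumerate_uninvadable(pool)
  rep1 <- monte_carlo_feasibility(pool, ui, model_config(n_samples = 5000),
                                  seed = 2)
  lab <- infer_stability(rep1)
  stats <- multistability_histogram(rep1, lab)
  center <- rep1$supply[, which.max(stats$V)]
  proj <- pca_state_projection(pool, ui, lab, center, n_samples = 100, seed = 6)

  expect_true(all(c("sample", "state_id", "label", "PC1", "PC2") %in% names(proj)))
  expect_gte(length(unique(proj$state_id[proj$label == "stable"])), max(stats$V))
  expect_equal(length(attr(proj, "var_explained")), 2)

  # points of the same state sit closer together than points of different states
  if (length(unique(proj$state_id)) >= 2) {
    cen <- aggregate(cbind(PC1, PC2) ~ state_id, proj, mean)
    within <- mean(vapply(seq_len(nrow(proj)), function(r) {
      ctr <- cen[cen$state_id == proj$state_id[r], c("PC1", "PC2")]
      sqrt(sum((proj[r, c("PC1", "PC2")] - ctr)^2))
    }, numeric(1)))
    between <- mean(dist(as.matrix(cen[, c("PC1", "PC2")])))
    expect_lt(within, between)
  }

  expect_error(pca_state_projection(pool, ui, lab, center, n_samples = 2),
               "at least 3")
})
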