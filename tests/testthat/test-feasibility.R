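test_that("the resource matrix reproduces the conservation-law pattern", {
  # three species B11, B12, B22 limited by n1, c1, c2 respectively; n2 free
  pool <- species_pool(data.frame(
    species_id = 1:4,
    i = c(1L, 1L, 2L, 2L), j = c(1L, 2L, 1L, 2L),
    lambda_c = c(80, 30, 55, 70), lambda_n = c(60, 35, 45, 20),
    yield_c = c(0.3, 0.5, 0.4, 0.6), yield_n = c(0.6, 0.4, 0.5, 0.3)
  ), K = 2, M = 2)
  state <- c(2L, 1L, 0L, 1L)   # B11 N-limited, B12 C-limited, B22 C-limited
  sp <- pool$species
  R <- build_resource_matrix(pool, state)
  expect_equal(dim(R), c(4, 4))
  expect_equal(colnames(R), c("B1", "B2", "B4", "n2"))
  Yc <- sp$yield_c; Yn <- sp$yield_n
  expected <- rbind(
    c(1 / Yc[1], 1 / Yc[2], 0,         0),   # c1: consumed by B11, B12
    c(0,         0,         1 / Yc[4], 0),   # c2: consumed by B22
    c(1 / Yn[1], 0,         0,         0),   # n1: consumed by B11
    c(0,         1 / Yn[2], 1 / Yn[4], 1)    # n2: consumed by B12, B22; free
  )
  expect_equal(unname(R), expected)

  # empty state: identity (all metabolites non-limiting)
  expect_equal(unname(build_resource_matrix(pool, rep(0L, 4))), diag(4))

  # single-species carbon-limited state in a 1C x 1N pool
  p1 <- generate_pool(1, 1, seed = 1)
  R1 <- build_resource_matrix(p1, 1L)
  expect_equal(unname(R1),
               rbind(c(1 / p1$species$yield_c, 0), c(1 / p1$species$yield_n, 1)))
})

test_that("solve_state does the two-line conservation algebra", {
  pool <- species_pool(data.frame(
    species_id = 1L, i = 1L, j = 1L,
    lambda_c = 50, lambda_n = 40, yield_c = 0.5, yield_n = 0.5
  ), K = 1, M = 1)
  cfg <- model_config()
  sol <- solve_state(pool, 1L, c(10, 20), cfg)
  expect_true(sol$feasible)
  expect_equal(sol$B[1], 0.5 * 10)             # B = Yc * phi_c / delta
  expect_equal(unname(sol$conc["n1"]), 20 - 5 / 0.5)  # n = phi_n/delta - B/Yn

  sol2 <- solve_state(pool, 1L, c(10, 8), cfg)
  expect_false(sol2$feasible)
  expect_equal(unname(sol2$conc["n1"]), -2)

  # mass conservation residual of the returned solution is machine-zero
  R <- build_resource_matrix(pool, 1L)
  expect_equal(as.numeric(R %*% sol$X), c(10, 20), tolerance = 1e-12)
})

test_that("supply sampling is uniform on the configured box and reproducible", {
  pool <- generate_pool(2, 2, seed = 1)
  cfg <- model_config()
  s1 <- sample_supply(pool, 5000, cfg, seed = 3)
  s2 <- sample_supply(pool, 5000, cfg, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 10 & s1 <= 1000))
  expect_equal(mean(rowMeans(s1)), 505, tolerance = 0.05)
  expect_error(model_config(supply_low = 1, supply_high = 1000), "high-supply")
})

test_that("Monte-Carlo feasible fractions match the analytic probability", {
  # one species with equal yields: its carbon-limited state is feasible iff
  # phi_n > phi_c, probability one half on the symmetric box
  pool <- species_pool(data.frame(
    species_id = 1L, i = 1L, j = 1L,
    lambda_c = 50, lambda_n = 40, yield_c = 0.4, yield_n = 0.4
  ), K = 1, M = 1)
  cfg <- model_config(n_samples = 4000)
  states <- rbind(1L)
  rep1 <- monte_carlo_feasibility(pool, states, cfg, seed = 11)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(rep1$fraction[1] - 0.5), 3 * se)

  # bookkeeping: per-sample indicator sums equal the per-state fractions
  expect_equal(length(rep1$feasible[[1]]) / rep1$n_samples, rep1$fraction[1])

  # convexity: the midpoint of two feasible supplies is feasible
  ids <- rep1$feasible[[1]][1:2]
  mid <- rowMeans(rep1$supply[, ids, drop = FALSE])
  expect_true(solve_state(pool, 1L, mid, cfg)$feasible)

  # determinism given the seed
  rep2 <- monte_carlo_feasibility(pool, states, cfg, seed = 11)
  expect_identical(rep1$feasible, rep2$feasible)
})

test_that("high-supply solutions track the exact ODE fixed point closely", {
  pool <- generate_pool(2, 2, seed = 2)
  cfg <- model_config()
  ui <- enumerate_uninvadable(pool)
  rep1 <- monte_carlo_feasibility(pool, ui, cfg, n_samples = 200, seed = 4)
  checked <- 0
  for (p in seq_len(nrow(ui))) {
    if (length(rep1$feasible[[p]]) == 0 || state_richness(ui[p, ]) == 0) next
    supply <- rep1$supply[, rep1$feasible[[p]][1]]
    hs <- solve_state(pool, ui[p, ], supply, cfg)
    ex <- solve_state(pool, ui[p, ], supply, cfg, exact = TRUE)
    present <- which(ui[p, ] > 0)
    expect_lt(max(abs(hs$B[present] - ex$B[present]) / ex$B[present]), 0.01)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("structural stability is a threshold call on the feasible range", {
  rep_fake <- structure(list(fraction = c(0.5, 0.05, 0.2, 0)),
                        class = "feasibility_report")
  expect_equal(classify_structural_stability(rep_fake),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(classify_structural_stability(rep_fake, threshold = 0),
               c(TRUE, TRUE, TRUE, FALSE))
})
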