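test_that("raw assignments enumerate the full 3^S cube", {
  pool <- generate_pool(2, 2, seed = 1)
  A <- candidate_assignments(pool)
  expect_equal(nrow(A), 81)

  one <- candidate_assignments(generate_pool(1, 1, seed = 0))
  expect_equal(nrow(one), 3)

  two <- candidate_assignments(generate_pool(1, 2, seed = 2))
  expect_equal(nrow(two), 9)
  expect_equal(anyDuplicated(state_key(two)), 0L)
})

test_that("the exclusion rules reject double limitation and uncompetitive non-limited users", {
  # two species on the same carbon; lambda_c of sp1 > sp2
  pool <- species_pool(data.frame(
    species_id = 1:2, i = 1L, j = 1:2,
    lambda_c = c(50, 40), lambda_n = c(30, 60),
    yield_c = 0.5, yield_n = 0.5
  ), K = 1, M = 2)

  both_c <- c(1L, 1L)  # both carbon-limited on c1: rule 1
  v <- satisfies_exclusion_rules(pool, both_c)
  expect_false(v)
  expect_match(attr(v, "violations"), "rule 1", all = FALSE)

  # sp2 carbon-limited, sp1 uses c1 non-limitingly with larger lambda_c: allowed
  expect_true(satisfies_exclusion_rules(pool, c(2L, 1L)))
  # the mirror image puts the weaker competitor non-limited: rule 2
  v <- satisfies_exclusion_rules(pool, c(1L, 2L))
  expect_false(v)

  expect_true(satisfies_exclusion_rules(pool, c(0L, 0L)))
})

test_that("a single-species pool has exactly three states, two of them uninvadable", {
  pool <- generate_pool(1, 1, seed = 0)
  ss <- enumerate_steady_states(pool)
  expect_equal(nrow(ss), 3)
  expect_setequal(state_key(ss), c("0", "1", "2"))

  ui <- brute_uninvadable(pool)
  expect_setequal(state_key(ui), c("1", "2"))
  expect_false(is_uninvadable(pool, 0L)$uninvadable)
  expect_setequal(state_key(enumerate_uninvadable(pool)), c("1", "2"))
})

test_that("structured enumeration equals the brute-force rule filter on random pools", {
  for (seed in 1:4) {
    for (L in 1:3) {
      pool <- generate_pool(L, L, seed = seed)
      ss <- enumerate_steady_states(pool)
      sb <- enumerate_steady_states(pool, method = "brute")
      expect_identical(state_key(ss), state_key(sb))
      expect_lte(nrow(ss), 3^pool$S)
      ok <- vapply(seq_len(nrow(ss)),
                   function(r) isTRUE(satisfies_exclusion_rules(pool, ss[r, ])),
                   logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("greedy uninvadable enumeration equals brute-force invasion testing", {
  for (seed in 5:8) {
    pool <- generate_pool(3, 3, seed = seed)
    expect_identical(state_key(enumerate_uninvadable(pool)),
                     state_key(brute_uninvadable(pool)))
  }
  # subset property and at most one uninvadable state per carbon selection
  pool <- generate_pool(3, 2, seed = 9)
  ui <- enumerate_uninvadable(pool)
  ss <- enumerate_steady_states(pool)
  expect_true(all(state_key(ui) %in% state_key(ss)))
  csel_key <- apply(ui, 1, function(s) paste(which(s == 1L), collapse = ","))
  expect_equal(anyDuplicated(csel_key), 0L)
})

test_that("greedy construction matches the enumerated state for its carbon selection", {
  pool <- generate_pool(2, 2, seed = 10)
  sp <- pool$species
  # top carbon competitor per carbon: the construction must succeed
  top <- vapply(1:2, function(i) {
    idx <- which(sp$i == i)
    sp$species_id[idx[which.max(sp$lambda_c[idx])]]
  }, integer(1))
  res <- construct_uninvadable(pool, top)
  expect_true(res$exists)
  expect_true(is_uninvadable(pool, res$state)$uninvadable)
  expect_true(state_key(res$state) %in% state_key(enumerate_uninvadable(pool)))

  # empty carbon selection in a two-species single-pair pool adds the better
  # nitrogen competitor
  tp <- tilman_pool()
  res <- construct_uninvadable(tp, NA_integer_)
  expect_true(res$exists)
  expect_equal(res$state, c(0L, 2L))  # species B has the larger lambda_n
})

test_that("enumeration is invariant under monotone rescaling of a lambda column", {
  pool <- generate_pool(3, 3, seed = 12)
  keys <- state_key(enumerate_steady_states(pool))
  ukeys <- state_key(enumerate_uninvadable(pool))
  sp <- pool$species
  idx <- sp$i == 2
  sp$lambda_c[idx] <- 10 + 90 * rank(sp$lambda_c[idx]) / sum(idx)  # order-preserving
  rescaled <- species_pool(sp)
  expect_identical(state_key(enumerate_steady_states(rescaled)), keys)
  expect_identical(state_key(enumerate_uninvadable(rescaled)), ukeys)
})

test_that("invadability follows the rank-order test", {
  # 2C x 2N x 4S with a known invader: state with sp2 (c1) and sp4 (c2) both
  # carbon-limited leaves n1 free; sp1 with the larger lambda_c invades
  pool <- species_pool(data.frame(
    species_id = 1:4,
    i = c(1L, 1L, 2L, 2L), j = c(1L, 2L, 1L, 2L),
    lambda_c = c(80, 40, 55, 70), lambda_n = c(30, 60, 45, 20),
    yield_c = c(0.3, 0.5, 0.4, 0.6), yield_n = c(0.6, 0.4, 0.5, 0.3)
  ), K = 2, M = 2)
  state <- c(0L, 1L, 0L, 1L)
  expect_true(satisfies_exclusion_rules(pool, state))
  res <- is_uninvadable(pool, state)
  expect_false(res$uninvadable)
  expect_true(1L %in% res$invaders)

  # a state limiting every metabolite with the pool-best species is uninvadable
  ui <- enumerate_uninvadable(pool)
  expect_gt(nrow(ui), 0)
  expect_true(all(vapply(seq_len(nrow(ui)),
                         function(r) is_uninvadable(pool, ui[r, ])$uninvadable,
                         logical(1))))
})
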