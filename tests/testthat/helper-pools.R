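# Fixtures built in code.

# Two species on one carbon/one nitrogen pair with crossed growth-yield
# ranking: the better carbon competitor (A) has the smaller carbon yield, the
# better nitrogen competitor (B) the smaller nitrogen yield. This is the
# classic two-species/two-essential-resources bistable configuration.
tilman_pool <- function() {
  species_pool(data.frame(
    species_id = 1:2, i = c(1L, 1L), j = c(1L, 1L),
    lambda_c = c(60, 30), lambda_n = c(20, 50),
    yield_c = c(0.2, 0.8), yield_n = c(0.8, 0.2)
  ), K = 1, M = 1)
}

# Random pool in which every species has the same C:N stoichiometry
# yield_n / yield_c.
equal_stoich_pool <- function(K, M, seed, ratio = 1) {
  pool <- generate_pool(K, M, seed = seed)
  sp <- pool$species
  sp$yield_n <- ratio * sp$yield_c
  species_pool(sp, K = K, M = M)
}

# Brute-force invasion filter: all steady states that pass the direct
# invadability test, via the 3^S enumeration.
brute_uninvadable <- function(pool) {
  ss <- enumerate_steady_states(pool, method = "brute")
  keep <- vapply(seq_len(nrow(ss)),
                 function(r) is_uninvadable(pool, ss[r, ])$uninvadable,
                 logical(1))
  ss[keep, , drop = FALSE]
}

# 2C x 2N x 4S pool whose lambda rank order admits the keystone bistable
# switch: {B11, B22} and {B12, B21} are both uninvadable, mutually exclusive
# pairs. Crossed yields make about half of supply space multistable.
keystone_pool <- function() {
  species_pool(data.frame(
    species_id = 1:4,
    i = c(1L, 1L, 2L, 2L), j = c(1L, 2L, 1L, 2L),   # B11, B12, B21, B22
    lambda_c = c(40, 80, 90, 30),
    lambda_n = c(85, 25, 35, 70),
    yield_c = c(0.2, 0.7, 0.6, 0.3),
    yield_n = c(0.7, 0.2, 0.3, 0.6)
  ), K = 2, M = 2)
}
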